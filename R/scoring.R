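#' Standardized completeness-of-reporting score for one domain
#'
#' The completeness score is the weighted fraction of pre-specified keywords
#' credited as reported, standardized to a 0-10 scale:
#' \deqn{S = 10 \sum_i w_i x_i / \sum_i w_i}
#' where \eqn{x_i = 1} if the keyword is present \emph{or} the writer
#' explicitly flagged the information as missing from the source protocol
#' (the missing-information rule: such keywords count as completely
#' reported). Standardization makes scores comparable across domains whose
#' rubrics have different numbers of keywords and weight scales; multiplying
#' every weight by a constant leaves the score unchanged.
#'
#' @param rubric A [domain_rubric()].
#' @param consensus Consensus keyword records (e.g. the `consensus` component
#'   of [merge_consensus()]); must cover every keyword of the rubric. Extra
#'   rows for other protocols/domains are ignored.
#' @return Numeric score in \[0, 10\].
#' @export
#' @examples
#' r <- domain_rubric("P1", "randomization", data.frame(
#'   id = c("a", "b", "c"), text = c("x", "y", "z"), weight = c(2, 1, 1)))
#' cons <- data.frame(protocol_id = "P1", domain = "randomization",
#'   keyword_id = c("a", "b", "c"), present = c(TRUE, FALSE, TRUE),
#'   flagged_missing = FALSE)
#' domain_score(r, cons)  # 10 * 3/4 = 7.5
domain_score <- function(rubric, consensus) {
  stopifnot(inherits(rubric, "domain_rubric"))
  x <- match_consensus(rubric, consensus)
  10 * sum(rubric$weight * x) / sum(rubric$weight)
}

#' Completeness score restricted to essential elements
#'
#' Same formula as [domain_score()] but over the keywords flagged
#' `essential`. Returns `NA` (not 0) when the rubric has no essential
#' keywords: an undefined subscore is not an empty report.
#'
#' @inheritParams domain_score
#' @return Numeric score in \[0, 10\], or `NA_real_` if no essential keywords.
#' @export
essential_score <- function(rubric, consensus) {
  stopifnot(inherits(rubric, "domain_rubric"))
  if (!any(rubric$essential)) return(NA_real_)
  x <- match_consensus(rubric, consensus)
  ess <- rubric$essential
  10 * sum(rubric$weight[ess] * x[ess]) / sum(rubric$weight[ess])
}

# Align consensus rows to the rubric's keywords; returns the credited
# indicator x_i = present | flagged_missing in rubric order.
match_consensus <- function(rubric, consensus) {
  cons <- as.data.frame(consensus, stringsAsFactors = FALSE)
  req <- c("keyword_id", "present", "flagged_missing")
  if (length(setdiff(req, names(cons)))) {
    stop("consensus lacks column(s): ",
         paste(setdiff(req, names(cons)), collapse = ", "), call. = FALSE)
  }
  if ("protocol_id" %in% names(cons)) {
    cons <- cons[cons$protocol_id == attr(rubric, "protocol_id"), ]
  }
  if ("domain" %in% names(cons)) {
    cons <- cons[cons$domain == attr(rubric, "domain"), ]
  }
  idx <- match(rubric$id, as.character(cons$keyword_id))
  if (anyNA(idx)) {
    stop("consensus does not cover keyword(s): ",
         paste(rubric$id[is.na(idx)], collapse = ", "),
         " (protocol '", attr(rubric, "protocol_id"), "', domain '",
         attr(rubric, "domain"), "')", call. = FALSE)
  }
  as.logical(cons$present[idx]) | as.logical(cons$flagged_missing[idx])
}

#' Score every domain of one or more protocols
#'
#' Convenience over [domain_score()] / [essential_score()]: applies the
#' matching rubric to each (protocol, domain) present in the consensus.
#'
#' @param rubrics A [protocol_rubric()] or a list of them.
#' @param consensus Consensus keyword records covering every rubric keyword.
#' @return `data.frame` with columns `protocol_id, domain, score,
#'   essential_score` (the latter `NA` where a domain has no essential
#'   keywords).
#' @export
score_consensus <- function(rubrics, consensus) {
  if (inherits(rubrics, "protocol_rubric")) rubrics <- list(rubrics)
  rows <- lapply(rubrics, function(pr) {
    stopifnot(inherits(pr, "protocol_rubric"))
    do.call(rbind, lapply(unname(pr), function(d) {
      data.frame(protocol_id = attr(d, "protocol_id"),
                 domain = attr(d, "domain"),
                 score = domain_score(d, consensus),
                 essential_score = essential_score(d, consensus),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate a domain-level score table
#'
#' The score table is the trial's analysis dataset: one row per participant,
#' domain and condition with the standardized 0-10 score. Balance is the
#' design invariant — every participant contributes exactly six rows, three
#' in the `tool` condition and three in `control`, one per domain.
#'
#' @param df `data.frame` with columns `participant_id, protocol_id, domain,
#'   condition, score` and optionally `essential_score`.
#' @return The validated `data.frame` (class `score_table` prepended).
#' @export
as_score_table <- function(df) {
  if (inherits(df, "score_table")) return(df)  # already validated
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("participant_id", "protocol_id", "domain", "condition", "score")
  if (length(setdiff(req, names(df)))) {
    stop("score table lacks column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  df$protocol_id <- as.character(df$protocol_id)
  df$domain <- as.character(df$domain)
  df$condition <- as.character(df$condition)
  df$score <- as.numeric(df$score)
  if (!"essential_score" %in% names(df)) df$essential_score <- NA_real_
  check_domain(df$domain)
  bad_cond <- setdiff(unique(df$condition), c("tool", "control"))
  if (length(bad_cond)) {
    stop("condition must be 'tool' or 'control', found: ",
         paste(bad_cond, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$score)) stop("missing scores in score table", call. = FALSE)
  tab <- table(df$participant_id, df$condition)
  bad <- rownames(tab)[tab[, "tool"] != 3L | tab[, "control"] != 3L]
  if (length(bad)) {
    stop("unbalanced participants (need 3 tool + 3 control rows): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  dup <- anyDuplicated(paste(df$participant_id, df$domain, sep = "\r"))
  if (dup) stop("participant/domain pairs duplicated in score table",
                call. = FALSE)
  if (!inherits(df, "score_table")) class(df) <- c("score_table", class(df))
  df
}

#' Per-participant and overall condition means
#'
#' The global completeness score for a participant under a condition is the
#' mean of their three per-domain scores in that condition; the trial-level
#' condition mean averages these over participants.
#'
#' @param table A balanced score table (see [as_score_table()]).
#' @return List with `per_participant` (`participant_id, mean_tool,
#'   mean_control, difference`) and `overall` (named numeric, `tool` and
#'   `control`).
#' @export
condition_means <- function(table) {
  table <- as_score_table(table)
  m <- tapply(table$score, list(table$participant_id, table$condition), mean)
  per <- data.frame(participant_id = rownames(m),
                    mean_tool = as.numeric(m[, "tool"]),
                    mean_control = as.numeric(m[, "control"]),
                    stringsAsFactors = FALSE)
  per$difference <- per$mean_tool - per$mean_control
  rownames(per) <- NULL
  list(per_participant = per,
       overall = c(tool = mean(per$mean_tool),
                   control = mean(per$mean_control)))
}

#' Read / write score tables
#'
#' CSV columns `participant_id, protocol_id, domain, condition, score,
#' essential_score`; an undefined essential subscore is an empty field.
#'
#' @param path CSV path.
#' @return `read_scores()`: a validated score table.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("scores file not found: ", path, call. = FALSE)
  as_score_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_scores
#' @param table Score table.
#' @export
write_scores <- function(table, path) {
  table <- as_score_table(table)
  utils::write.csv(
    table[, c("participant_id", "protocol_id", "domain", "condition",
              "score", "essential_score")],
    path, row.names = FALSE, na = "")
  invisible(path)
}

normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:]]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Deterministic keyword matcher for synthetic raters
#'
#' A mechanical stand-in for a human assessor, used in demos and synthetic
#' end-to-end pipelines: a keyword is `present` when its normalized text
#' (case-folded, punctuation stripped, whitespace collapsed) occurs as a
#' substring of the normalized input, and `flagged_missing` when the raw text
#' contains an explicit bracketed marker `[missing: <keyword id>]`. No
#' stemming or fuzzy matching; the study itself used human raters.
#'
#' @param rubric A [domain_rubric()].
#' @param text Free text of the written domain.
#' @param rater_id Identifier recorded on the emitted ratings.
#' @return Rating records (one row per rubric keyword).
#' @export
auto_match <- function(rubric, text, rater_id = "auto") {
  stopifnot(inherits(rubric, "domain_rubric"), is.character(text),
            length(text) == 1L)
  norm <- normalize_text(text)
  present <- vapply(rubric$text, function(kw) {
    nk <- normalize_text(kw)
    nzchar(nk) && grepl(nk, norm, fixed = TRUE)
  }, logical(1))
  markers <- regmatches(text,
                        gregexpr("\\[\\s*missing\\s*:?[^]]*\\]", text,
                                 ignore.case = TRUE))[[1L]]
  marked <- normalize_text(paste(markers, collapse = " "))
  flagged <- vapply(rubric$id, function(id) {
    nid <- normalize_text(id)
    nzchar(marked) && nzchar(nid) &&
      grepl(paste0("\\b", nid, "\\b"), marked)
  }, logical(1))
  data.frame(protocol_id = attr(rubric, "protocol_id"),
             domain = attr(rubric, "domain"),
             rater_id = rater_id, keyword_id = rubric$id,
             present = unname(present), flagged_missing = unname(flagged),
             stringsAsFactors = FALSE)
}
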