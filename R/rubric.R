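#' Build a domain rubric
#'
#' A domain rubric is the pre-specified, weighted keyword checklist against
#' which one methods-section domain of one protocol is scored. Each keyword
#' carries a positive weight \eqn{w_i} and an `essential` flag marking the
#' must-report elements scored separately as a secondary outcome.
#'
#' @param protocol_id Protocol identifier (single string).
#' @param domain One of [trial_domains()].
#' @param keywords `data.frame` with columns `id`, `text`, `weight` and
#'   optionally `essential` (default `FALSE`). Row order is preserved and is
#'   the tie-break order used elsewhere (e.g. [realize_keywords()]).
#' @return An object of class `domain_rubric`: the keyword `data.frame` with
#'   attributes `protocol_id` and `domain`.
#' @export
#' @examples
#' domain_rubric("P001", "randomization", data.frame(
#'   id = c("computer", "blocks4", "ratio", "strat"),
#'   text = c("Computer generated", "blocks of 4", "1:1",
#'            "stratification on site"),
#'   weight = c(2, 1, 1, 1)))
domain_rubric <- function(protocol_id, domain, keywords) {
  stopifnot(is.character(protocol_id), length(protocol_id) == 1L,
            length(domain) == 1L)
  check_domain(domain)
  keywords <- as.data.frame(keywords, stringsAsFactors = FALSE)
  req <- c("id", "text", "weight")
  missing_cols <- setdiff(req, names(keywords))
  if (length(missing_cols)) {
    stop("keyword table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(keywords)) stop("rubric for domain '", domain,
                            "' must have at least one keyword", call. = FALSE)
  if (!"essential" %in% names(keywords)) keywords$essential <- FALSE
  keywords$id <- as.character(keywords$id)
  keywords$text <- as.character(keywords$text)
  keywords$weight <- as.numeric(keywords$weight)
  keywords$essential <- as.logical(keywords$essential)
  if (anyDuplicated(keywords$id)) {
    stop("duplicate keyword id(s) in domain '", domain, "': ",
         paste(unique(keywords$id[duplicated(keywords$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_w <- !is.finite(keywords$weight) | keywords$weight <= 0
  if (any(bad_w)) {
    stop("non-positive weight for keyword(s): ",
         paste(keywords$id[bad_w], collapse = ", "),
         " (domain '", domain, "')", call. = FALSE)
  }
  if (any(!nzchar(keywords$text))) {
    stop("empty keyword text for id(s): ",
         paste(keywords$id[!nzchar(keywords$text)], collapse = ", "),
         call. = FALSE)
  }
  check_flag(keywords$essential, "essential")
  keywords <- keywords[, c("id", "text", "weight", "essential")]
  rownames(keywords) <- NULL
  structure(keywords, protocol_id = protocol_id, domain = domain,
            class = c("domain_rubric", "data.frame"))
}

#' Build a protocol rubric (all six domains)
#'
#' @param protocol_id Protocol identifier.
#' @param domains List of six [domain_rubric()] objects, one per domain of
#'   [trial_domains()], no duplicates.
#' @return Object of class `protocol_rubric`: a named list of domain rubrics
#'   in canonical domain order.
#' @export
protocol_rubric <- function(protocol_id, domains) {
  stopifnot(is.list(domains))
  if (!all(vapply(domains, inherits, logical(1), "domain_rubric"))) {
    stop("`domains` must be a list of domain_rubric objects", call. = FALSE)
  }
  doms <- vapply(domains, attr, character(1), "domain")
  if (anyDuplicated(doms)) {
    stop("duplicated domain rubric(s): ",
         paste(unique(doms[duplicated(doms)]), collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(trial_domains(), doms)
  if (length(absent)) {
    stop("protocol rubric '", protocol_id, "' is missing domain(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  for (d in domains) {
    if (!identical(attr(d, "protocol_id"), protocol_id)) {
      stop("domain rubric protocol_id '", attr(d, "protocol_id"),
           "' does not match '", protocol_id, "'", call. = FALSE)
    }
  }
  names(domains) <- doms
  structure(domains[trial_domains()], protocol_id = protocol_id,
            class = "protocol_rubric")
}

#' @export
print.protocol_rubric <- function(x, ...) {
  cat("Protocol rubric", attr(x, "protocol_id"), "\n")
  for (d in names(x)) {
    cat(sprintf("  %-14s %2d keywords, total weight %g, %d essential\n",
                d, nrow(x[[d]]), sum(x[[d]]$weight), sum(x[[d]]$essential)))
  }
  invisible(x)
}

rubric_from_flat <- function(flat) {
  req <- c("protocol_id", "domain", "keyword_id", "text", "weight", "essential")
  missing_cols <- setdiff(req, names(flat))
  if (length(missing_cols)) {
    stop("rubric table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pid <- unique(as.character(flat$protocol_id))
  if (length(pid) != 1L) {
    stop("rubric file must describe exactly one protocol, found: ",
         paste(pid, collapse = ", "), call. = FALSE)
  }
  check_domain(flat$domain)
  pieces <- split(flat, factor(flat$domain, levels = unique(flat$domain)))
  domains <- lapply(pieces, function(p) {
    domain_rubric(pid, as.character(p$domain[1L]),
                  data.frame(id = p$keyword_id, text = p$text,
                             weight = p$weight,
                             essential = as.logical(p$essential)))
  })
  protocol_rubric(pid, unname(domains))
}

rubric_to_flat <- function(rubric) {
  stopifnot(inherits(rubric, "protocol_rubric"))
  do.call(rbind, lapply(unname(rubric), function(d) {
    data.frame(protocol_id = attr(d, "protocol_id"),
               domain = attr(d, "domain"),
               keyword_id = d$id, text = d$text, weight = d$weight,
               essential = d$essential, stringsAsFactors = FALSE)
  }))
}

#' Read a protocol rubric from JSON or CSV
#'
#' Two on-disk forms are accepted, detected by file extension. JSON nests a
#' `domains` map of keyword arrays under one `protocol_id`; CSV is the flat
#' table `protocol_id, domain, keyword_id, text, weight, essential`. Weights
#' are retained exactly as given; writing then reading a rubric reproduces
#' weights, flags and keyword order.
#'
#' @param path Path to a `.json` or `.csv` rubric file.
#' @return A [protocol_rubric()].
#' @seealso [write_rubric()]
#' @export
read_rubric <- function(path) {
  if (!file.exists(path)) stop("rubric file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(doc$protocol_id) || is.null(doc$domains)) {
      stop("rubric JSON must have 'protocol_id' and 'domains'", call. = FALSE)
    }
    pid <- as.character(doc$protocol_id)
    domains <- lapply(names(doc$domains), function(dn) {
      kws <- doc$domains[[dn]]$keywords %||% doc$domains[[dn]]
      kw <- data.frame(
        id = vapply(kws, function(k) as.character(k$id), character(1)),
        text = vapply(kws, function(k) as.character(k$text), character(1)),
        weight = vapply(kws, function(k) as.numeric(k$weight), numeric(1)),
        essential = vapply(kws, function(k) isTRUE(k$essential), logical(1)),
        stringsAsFactors = FALSE)
      domain_rubric(pid, dn, kw)
    })
    protocol_rubric(pid, domains)
  } else if (ext == "csv") {
    rubric_from_flat(utils::read.csv(path, stringsAsFactors = FALSE))
  } else {
    stop("unsupported rubric format '.", ext, "' (use .json or .csv)",
         call. = FALSE)
  }
}

#' Write a protocol rubric to JSON or CSV
#'
#' @param rubric A [protocol_rubric()].
#' @param path Destination `.json` or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_rubric <- function(rubric, path) {
  stopifnot(inherits(rubric, "protocol_rubric"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- list(
      protocol_id = attr(rubric, "protocol_id"),
      domains = lapply(rubric, function(d) {
        list(keywords = lapply(seq_len(nrow(d)), function(i) {
          list(id = d$id[i], text = d$text[i], weight = d$weight[i],
               essential = d$essential[i])
        }))
      }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext == "csv") {
    utils::write.csv(rubric_to_flat(rubric), path, row.names = FALSE)
  } else {
    stop("unsupported rubric format '.", ext, "' (use .json or .csv)",
         call. = FALSE)
  }
  invisible(path)
}

#' Read / write rater keyword records
#'
#' Ratings are the keyword-level presence judgements of the blinded outcome
#' assessors: one row per (protocol, domain, keyword, rater) with `present`
#' and `flagged_missing` indicators, 0/1 on disk. `flagged_missing` records
#' that the writer explicitly noted the information as absent from the source
#' protocol, which the scoring rule credits as completely reported.
#'
#' @param path CSV path with columns `protocol_id, domain, rater_id,
#'   keyword_id, present, flagged_missing`.
#' @return `read_ratings()`: a validated `data.frame` with logical `present`
#'   and `flagged_missing`.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ratings(df)
}

#' @rdname read_ratings
#' @param ratings Ratings `data.frame` as returned by [read_ratings()] or
#'   [auto_match()].
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  out <- ratings
  out$present <- as.integer(out$present)
  out$flagged_missing <- as.integer(out$flagged_missing)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

validate_ratings <- function(df) {
  req <- c("protocol_id", "domain", "rater_id", "keyword_id",
           "present", "flagged_missing")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("ratings lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$protocol_id <- as.character(df$protocol_id)
  df$domain <- as.character(df$domain)
  df$rater_id <- as.character(df$rater_id)
  df$keyword_id <- as.character(df$keyword_id)
  df$present <- as.logical(df$present)
  df$flagged_missing <- as.logical(df$flagged_missing)
  check_domain(df$domain)
  check_flag(df$present, "present")
  check_flag(df$flagged_missing, "flagged_missing")
  key <- paste(df$protocol_id, df$domain, df$keyword_id, df$rater_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (protocol, domain, keyword, rater) rating rows",
         call. = FALSE)
  }
  df
}

rating_key <- function(df) {
  paste(df$protocol_id, df$domain, df$keyword_id, sep = "\r")
}

#' Merge two raters' keyword records into a consensus
#'
#' Two independent assessors rate every keyword; agreements are copied
#' through, disagreements are settled by explicit consensus resolutions, and
#' anything still unresolved is reported rather than silently decided. A
#' disagreement is any difference in `present` or `flagged_missing` for the
#' same (protocol, domain, keyword).
#'
#' @param ratings Rating records from exactly two raters covering identical
#'   (protocol, domain, keyword) keys.
#' @param resolutions Optional `data.frame` of adjudicated values with
#'   columns `protocol_id, domain, keyword_id, present, flagged_missing`.
#' @return List with components `consensus` (one row per key that was agreed
#'   or resolved; `resolved` marks adjudicated rows) and `disagreements`
#'   (unresolved keys with both raters' values, excluded from `consensus`).
#' @export
merge_consensus <- function(ratings, resolutions = NULL) {
  ratings <- validate_ratings(ratings)
  raters <- sort(unique(ratings$rater_id))
  if (length(raters) != 2L) {
    stop("consensus requires exactly two raters, found ", length(raters),
         " (", paste(raters, collapse = ", "), ")", call. = FALSE)
  }
  r1 <- ratings[ratings$rater_id == raters[1L], ]
  r2 <- ratings[ratings$rater_id == raters[2L], ]
  k1 <- rating_key(r1); k2 <- rating_key(r2)
  only1 <- setdiff(k1, k2); only2 <- setdiff(k2, k1)
  if (length(only1) || length(only2)) {
    miss <- gsub("\r", "/", c(only1, only2))
    stop("raters do not cover identical keys; unmatched: ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) " ..." else "", call. = FALSE)
  }
  r2 <- r2[match(k1, k2), ]
  agree <- r1$present == r2$present & r1$flagged_missing == r2$flagged_missing

  consensus <- data.frame(protocol_id = r1$protocol_id, domain = r1$domain,
                          keyword_id = r1$keyword_id, present = r1$present,
                          flagged_missing = r1$flagged_missing,
                          resolved = FALSE, stringsAsFactors = FALSE)
  keep <- agree
  if (any(!agree)) {
    if (!is.null(resolutions)) {
      res <- as.data.frame(resolutions, stringsAsFactors = FALSE)
      req <- c("protocol_id", "domain", "keyword_id", "present",
               "flagged_missing")
      if (length(setdiff(req, names(res)))) {
        stop("resolutions lack column(s): ",
             paste(setdiff(req, names(res)), collapse = ", "), call. = FALSE)
      }
      rk <- paste(res$protocol_id, res$domain, res$keyword_id, sep = "\r")
      hit <- match(k1, rk)
      use <- !agree & !is.na(hit)
      consensus$present[use] <- as.logical(res$present[hit[use]])
      consensus$flagged_missing[use] <- as.logical(res$flagged_missing[hit[use]])
      consensus$resolved[use] <- TRUE
      keep <- keep | use
    }
  }
  disagreements <- data.frame(
    protocol_id = r1$protocol_id, domain = r1$domain,
    keyword_id = r1$keyword_id,
    present_rater1 = r1$present, present_rater2 = r2$present,
    flagged_rater1 = r1$flagged_missing, flagged_rater2 = r2$flagged_missing,
    stringsAsFactors = FALSE)[!keep, ]
  rownames(disagreements) <- NULL
  out_cons <- consensus[keep, ]
  rownames(out_cons) <- NULL
  list(consensus = out_cons, disagreements = disagreements)
}
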