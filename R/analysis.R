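#' Primary intervention-effect estimate
#'
#' Estimates the writing-aid effect under the split-manuscript mixed model
#' \deqn{y_{pgj} = \mu + \beta T_g + b_p + c_{pg} + e_{pgj}}
#' with a random participant effect \eqn{b_p} and a random
#' participant-by-condition ("participant-group") effect \eqn{c_{pg}}.
#' With a balanced table (three domains per condition per participant) the
#' generalized-least-squares solution reduces exactly to the paired
#' contrast: \eqn{\hat\beta} is the mean over participants of
#' \eqn{d_p = \bar y_{p,tool} - \bar y_{p,control}}, its standard error
#' \eqn{sd(d_p)/\sqrt{N}}, with t-based CI and P on \eqn{N - 1} degrees of
#' freedom. An iterative REML fit is therefore unnecessary for estimation
#' (it is used only as a cross-check in the package's tests).
#'
#' @param table Balanced score table (see [as_score_table()]), at least two
#'   participants.
#' @param conf_level Two-sided confidence level (default 0.95).
#' @return Object of class `effect_estimate`: `beta_hat`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `df`, `n_participants`, `conf_level`.
#' @export
#' @examples
#' trial <- generate_trial(simulation_config(n_participants = 40, seed = 1))
#' primary_effect(trial$scores)
primary_effect <- function(table, conf_level = 0.95) {
  table <- as_score_table(table)
  cm <- condition_means(table)
  d <- cm$per_participant$difference
  n <- length(d)
  if (n < 2L) stop("need at least 2 participants to estimate a variance",
                   call. = FALSE)
  beta_hat <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    stop("degenerate data: all participant differences identical ",
         "(zero variance); no inference possible", call. = FALSE)
  }
  se <- sdd / sqrt(n)
  df <- n - 1L
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  tstat <- beta_hat / se
  structure(list(beta_hat = beta_hat, se = se,
                 ci_low = beta_hat - tcrit * se,
                 ci_high = beta_hat + tcrit * se,
                 p_value = 2 * stats::pt(-abs(tstat), df),
                 df = df, n_participants = n, conf_level = conf_level),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "Intervention effect: %.3f (%.0f%% CI %.3f to %.3f), SE %.3f\n",
    x$beta_hat, 100 * x$conf_level, x$ci_low, x$ci_high, x$se))
  cat(sprintf("  t(%d), P = %.4g, N = %d participants\n",
              x$df, x$p_value, x$n_participants))
  invisible(x)
}

#' ANOVA-type variance components of the split-manuscript model
#'
#' Method-of-moments estimators for the balanced two-way layout
#' (participant crossed with condition, `m` scores per cell), from the three
#' mean squares: between participants (`MSA`), participant-by-condition
#' interaction (`MSB`, with the fixed condition effect removed), and
#' residual (`MSE`):
#' \deqn{\hat\sigma^2_e = MSE,\quad \hat\sigma^2_c = (MSB - MSE)/m,\quad
#'       \hat\sigma^2_b = (MSA - MSB)/(2m).}
#' Negative solutions are truncated at zero and flagged. The implied
#' correlations are \eqn{\rho = (\sigma^2_b + \sigma^2_c)/\sigma^2} and
#' \eqn{\rho' = \sigma^2_b/\sigma^2} with
#' \eqn{\sigma^2 = \sigma^2_b + \sigma^2_c + \sigma^2_e}.
#'
#' @param table Balanced score table with at least 3 participants.
#' @return Object of class `variance_components`: `sigma2_b`, `sigma2_c`,
#'   `sigma2_e`, `sigma2_total`, `rho`, `rho_prime`, `truncated`.
#' @export
fit_variance_components <- function(table) {
  table <- as_score_table(table)
  n <- length(unique(table$participant_id))
  if (n < 3L) stop("need at least 3 participants", call. = FALSE)
  m <- 3L
  cell <- tapply(table$score, list(table$participant_id, table$condition),
                 mean)                       # N x 2 cell means
  p_mean <- rowMeans(cell)
  g_mean <- colMeans(cell)
  grand <- mean(cell)
  msa <- 2 * m * sum((p_mean - grand)^2) / (n - 1)
  resid_int <- sweep(sweep(cell, 1, p_mean), 2, g_mean) + grand
  msb <- m * sum(resid_int^2) / (n - 1)
  cell_of <- cell[cbind(table$participant_id, table$condition)]
  mse <- sum((table$score - cell_of)^2) / (2 * n * (m - 1))
  raw_c <- (msb - mse) / m
  raw_b <- (msa - msb) / (2 * m)
  truncated <- raw_c < 0 || raw_b < 0
  s2_c <- max(raw_c, 0)
  s2_b <- max(raw_b, 0)
  s2_tot <- s2_b + s2_c + mse
  structure(list(sigma2_b = s2_b, sigma2_c = s2_c, sigma2_e = mse,
                 sigma2_total = s2_tot,
                 rho = if (s2_tot > 0) (s2_b + s2_c) / s2_tot else NA_real_,
                 rho_prime = if (s2_tot > 0) s2_b / s2_tot else NA_real_,
                 truncated = truncated),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (participant / participant-by-condition / residual)\n")
  cat(sprintf("  sigma2_b = %.3f, sigma2_c = %.3f, sigma2_e = %.3f\n",
              x$sigma2_b, x$sigma2_c, x$sigma2_e))
  cat(sprintf("  total %.3f; implied rho = %.3f, rho' = %.3f%s\n",
              x$sigma2_total, x$rho, x$rho_prime,
              if (x$truncated) " [truncated at 0]" else ""))
  invisible(x)
}

#' Per-domain Student t-test
#'
#' Because each participant contributes a given domain to exactly one
#' condition, the domain-wise comparison is between independent groups of
#' participants, so the classical equal-variance two-sample Student t-test
#' applies. No multiplicity adjustment is made.
#'
#' @param table Score table.
#' @param domain One of [trial_domains()].
#' @param conf_level Confidence level for the CI on the mean difference.
#' @return `data.frame` (one row) with `domain, n_tool, n_control,
#'   mean_tool, mean_control, mean_difference, ci_low, ci_high, p_value`.
#' @export
per_domain_ttest <- function(table, domain, conf_level = 0.95) {
  table <- as_score_table(table)
  check_domain(domain)
  stopifnot(length(domain) == 1L)
  sub <- table[table$domain == domain, ]
  tool <- sub$score[sub$condition == "tool"]
  ctrl <- sub$score[sub$condition == "control"]
  if (length(tool) < 2L || length(ctrl) < 2L) {
    stop("domain '", domain, "': need at least 2 observations per condition ",
         "(got ", length(tool), " tool, ", length(ctrl), " control)",
         call. = FALSE)
  }
  tt <- stats::t.test(tool, ctrl, var.equal = TRUE,
                      conf.level = conf_level)
  data.frame(domain = domain, n_tool = length(tool),
             n_control = length(ctrl),
             mean_tool = mean(tool), mean_control = mean(ctrl),
             mean_difference = mean(tool) - mean(ctrl),
             ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L],
             p_value = tt$p.value, stringsAsFactors = FALSE)
}

#' @rdname per_domain_ttest
#' @return `all_domain_ttests()`: one row per domain.
#' @export
all_domain_ttests <- function(table, conf_level = 0.95) {
  out <- do.call(rbind, lapply(trial_domains(), per_domain_ttest,
                               table = table, conf_level = conf_level))
  rownames(out) <- NULL
  out
}

#' Paired comparison against published reports
#'
#' Ancillary analysis: within one condition subset, the participant's score
#' for each (protocol, domain) is paired with the score of the corresponding
#' published article. Differences (participant minus publication) are
#' averaged within protocol; the intercept of the random-protocol-intercept
#' model is then the mean of the per-protocol mean differences, with
#' standard error from the between-protocol variability and a t-based CI on
#' `n_protocols - 1` degrees of freedom (the exact balanced-case solution of
#' the stated mixed model).
#'
#' @param participant_scores Score table of the trial participants.
#' @param published_scores `data.frame` with columns `protocol_id, domain,
#'   score`: the published article's completeness scores, which must cover
#'   every (protocol, domain) in the chosen subset.
#' @param condition `"tool"` or `"control"`: which participant-written
#'   domains to compare.
#' @param conf_level Confidence level.
#' @return Object of class `ancillary_result`: `condition,
#'   mean_paired_difference, se, ci_low, ci_high, p_value, df, n_protocols,
#'   n_pairs`.
#' @export
ancillary_comparison <- function(participant_scores, published_scores,
                                 condition = c("tool", "control"),
                                 conf_level = 0.95) {
  condition <- match.arg(condition)
  table <- as_score_table(participant_scores)
  pub <- as.data.frame(published_scores, stringsAsFactors = FALSE)
  req <- c("protocol_id", "domain", "score")
  if (length(setdiff(req, names(pub)))) {
    stop("published scores lack column(s): ",
         paste(setdiff(req, names(pub)), collapse = ", "), call. = FALSE)
  }
  sub <- table[table$condition == condition, ]
  idx <- match(paste(sub$protocol_id, sub$domain, sep = "\r"),
               paste(pub$protocol_id, pub$domain, sep = "\r"))
  if (anyNA(idx)) {
    miss <- sub[is.na(idx), c("protocol_id", "domain")]
    stop("no published score for: ",
         paste(utils::head(paste(miss$protocol_id, miss$domain, sep = "/"),
                           5L), collapse = ", "),
         if (nrow(miss) > 5L) " ..." else "", call. = FALSE)
  }
  diff <- sub$score - as.numeric(pub$score)[idx]
  per_protocol <- tapply(diff, sub$protocol_id, mean)
  k <- length(per_protocol)
  if (k < 2L) {
    stop("need at least 2 protocols for a standard error (got ", k, ")",
         call. = FALSE)
  }
  est <- mean(per_protocol)
  se <- stats::sd(per_protocol) / sqrt(k)
  df <- k - 1L
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  p <- if (se > 0) 2 * stats::pt(-abs(est / se), df) else NA_real_
  structure(list(condition = condition, mean_paired_difference = est,
                 se = se, ci_low = est - tcrit * se,
                 ci_high = est + tcrit * se, p_value = p, df = df,
                 n_protocols = k, n_pairs = length(diff),
                 conf_level = conf_level),
            class = "ancillary_result")
}

#' @export
print.ancillary_result <- function(x, ...) {
  cat(sprintf(
    "Participant minus publication (%s domains): %.3f (%.0f%% CI %.3f to %.3f)\n",
    x$condition, x$mean_paired_difference, 100 * x$conf_level,
    x$ci_low, x$ci_high))
  cat(sprintf("  t(%d), P = %.4g, %d protocols / %d pairs\n",
              x$df, x$p_value, x$n_protocols, x$n_pairs))
  invisible(x)
}
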