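#' Variance components implied by the ICC parametrization
#'
#' The design's correlation assumptions map one-to-one onto the three
#' variance components of the split-manuscript model:
#' \deqn{\sigma^2_b = \rho'\sigma^2,\quad \sigma^2_c = (\rho-\rho')\sigma^2,
#'       \quad \sigma^2_e = (1-\rho)\sigma^2,}
#' so that two scores from the same participant correlate \eqn{\rho} under
#' the same condition and \eqn{\rho'} across conditions, with total variance
#' \eqn{\sigma^2}. At the study values (\eqn{\sigma} = 4, \eqn{\rho} = 0.8,
#' \eqn{\rho'} = 0.4) the components are (6.4, 6.4, 3.2).
#'
#' @param sigma_total Total per-domain score SD (> 0).
#' @param rho Within-condition intraclass correlation.
#' @param rho_prime Cross-condition correlation (`0 <= rho_prime <= rho <= 1`).
#' @return Object of class `variance_components` (see
#'   [fit_variance_components()]); `truncated` is `FALSE`.
#' @export
#' @examples
#' variance_components_from_icc(4, 0.8, 0.4)
variance_components_from_icc <- function(sigma_total, rho, rho_prime) {
  stopifnot(is.numeric(sigma_total), sigma_total > 0)
  if (!(rho_prime >= 0 && rho_prime <= rho && rho <= 1)) {
    stop("need 0 <= rho_prime <= rho <= 1 (got rho = ", rho,
         ", rho_prime = ", rho_prime, ")", call. = FALSE)
  }
  s2 <- sigma_total^2
  structure(list(sigma2_b = rho_prime * s2,
                 sigma2_c = (rho - rho_prime) * s2,
                 sigma2_e = (1 - rho) * s2,
                 sigma2_total = s2, rho = rho, rho_prime = rho_prime,
                 truncated = FALSE),
            class = "variance_components")
}

#' Configuration of the synthetic trial generator
#'
#' Defaults are the study conditions: 40 participants (the calculated sample
#' size), control condition mean 5.0 and intervention effect 2.1 (the
#' observed condition means 5.0 and 7.1), total SD 4, within-condition ICC
#' 0.8, cross-condition correlation 0.4, exchangeable domains (no per-domain
#' offsets) and no clipping. `clip_mode = "truncate"` clamps scores to the
#' 0-10 scale for realistic-looking demo data, at the cost of biasing the
#' moments the unclipped normal model targets.
#'
#' @param n_participants Number of participants.
#' @param mu_control Control-condition mean score.
#' @param beta Intervention effect added under the tool condition.
#' @param sigma_total Total per-domain score SD (> 0; 0 allowed for the
#'   deterministic degenerate case).
#' @param rho,rho_prime Correlation structure, as in
#'   [variance_components_from_icc()].
#' @param domain_effects Optional named numeric of six per-domain offsets
#'   summing to zero (names = [trial_domains()]).
#' @param clip_mode `"none"` (default) or `"truncate"`.
#' @param seed Seed for reproducible generation (`NULL` = ambient RNG).
#' @param n_replicates Replicates for simulation drivers (>= 1).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 40, mu_control = 5.0,
                              beta = 2.1, sigma_total = 4, rho = 0.8,
                              rho_prime = 0.4, domain_effects = NULL,
                              clip_mode = c("none", "truncate"),
                              seed = NULL, n_replicates = 1L) {
  clip_mode <- match.arg(clip_mode)
  stopifnot(n_participants >= 1, n_participants == round(n_participants),
            is.numeric(sigma_total), sigma_total >= 0,
            n_replicates >= 1)
  if (sigma_total > 0 &&
      !(rho_prime >= 0 && rho_prime <= rho && rho <= 1)) {
    stop("need 0 <= rho_prime <= rho <= 1", call. = FALSE)
  }
  if (!is.null(domain_effects)) {
    if (length(domain_effects) != 6L) {
      stop("domain_effects must have length 6", call. = FALSE)
    }
    if (is.null(names(domain_effects))) names(domain_effects) <- trial_domains()
    if (!setequal(names(domain_effects), trial_domains())) {
      stop("domain_effects names must be the six trial domains", call. = FALSE)
    }
    if (abs(sum(domain_effects)) > 1e-9) {
      stop("domain_effects must sum to 0 (got ", sum(domain_effects), ")",
           call. = FALSE)
    }
    domain_effects <- domain_effects[trial_domains()]
  }
  structure(list(n_participants = as.integer(n_participants),
                 mu_control = mu_control, beta = beta,
                 sigma_total = sigma_total, rho = rho,
                 rho_prime = rho_prime, domain_effects = domain_effects,
                 clip_mode = clip_mode, seed = seed,
                 n_replicates = as.integer(n_replicates)),
            class = "simulation_config")
}

#' Generate a synthetic split-manuscript trial
#'
#' Realizes the model the analysis assumes:
#' \deqn{y_{pd} = \mu_{control} + \beta T_{pd} + \delta_d + b_p + c_{pg} +
#'       e_{pd}}
#' with independent zero-mean normal participant, participant-by-condition
#' and residual effects at the variances implied by
#' [variance_components_from_icc()]. Allocation comes from the package's own
#' permuted-block randomization; each participant is assigned a distinct
#' synthetic protocol id. When `rubrics` is supplied, keyword-level rating
#' records consistent with the (0-10-clamped) scores are realized via
#' [realize_keywords()] so keyword-level pipelines run end to end.
#'
#' @param config A [simulation_config()].
#' @param rubrics Optional [protocol_rubric()] (shared by all participants)
#'   used to realize keyword-level ratings.
#' @return Object of class `synthetic_trial`: list with `allocation`,
#'   `scores` (a balanced score table), optional `ratings`, and `config`.
#' @export
#' @examples
#' trial <- generate_trial(simulation_config(n_participants = 6, seed = 42))
#' head(trial$scores)
generate_trial <- function(config, rubrics = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_participants
    vc <- if (config$sigma_total > 0) {
      variance_components_from_icc(config$sigma_total, config$rho,
                                   config$rho_prime)
    } else {
      list(sigma2_b = 0, sigma2_c = 0, sigma2_e = 0)
    }
    alloc <- generate_sequence(n)
    alloc$protocol_id <- sprintf("SP%03d", sample.int(n))[
      alloc$participant_index]
    b <- stats::rnorm(n, 0, sqrt(vc$sigma2_b))
    cmat <- matrix(stats::rnorm(2L * n, 0, sqrt(vc$sigma2_c)), nrow = n,
                   ncol = 2L)  # col 1 = control, col 2 = tool
    e <- stats::rnorm(nrow(alloc), 0, sqrt(vc$sigma2_e))
    p <- alloc$participant_index
    tool <- alloc$condition == "tool"
    delta <- if (is.null(config$domain_effects)) 0 else
      unname(config$domain_effects[alloc$domain])
    y <- config$mu_control + config$beta * tool + delta +
      b[p] + cmat[cbind(p, 1L + tool)] + e
    if (config$clip_mode == "truncate") y <- pmin(pmax(y, 0), 10)
    scores <- data.frame(
      participant_id = sprintf("S%03d", alloc$participant_index),
      protocol_id = alloc$protocol_id, domain = alloc$domain,
      condition = alloc$condition, score = y,
      stringsAsFactors = FALSE)
    trial <- list(allocation = alloc, scores = as_score_table(scores),
                  config = config)
    if (!is.null(rubrics)) {
      stopifnot(inherits(rubrics, "protocol_rubric"))
      trial$ratings <- do.call(rbind, lapply(seq_len(nrow(scores)),
        function(i) {
          rub <- rubrics[[scores$domain[i]]]
          target <- min(max(scores$score[i], 0), 10)
          sel <- realize_keywords(rub, target)
          data.frame(protocol_id = scores$protocol_id[i],
                     domain = scores$domain[i], rater_id = "synthetic",
                     keyword_id = sel$keyword_id, present = sel$present,
                     flagged_missing = FALSE, stringsAsFactors = FALSE)
        }))
    }
    structure(trial, class = "synthetic_trial")
  })
}

#' Realize a keyword presence vector hitting a target score
#'
#' Greedy largest-weight-first selection: keywords are considered in
#' decreasing weight order (rubric order breaks ties) and taken whenever the
#' cumulative standardized score stays at or below the target. The realized
#' score never exceeds the target and falls short by at most
#' \eqn{10\,w_{max}/\sum_i w_i}, the resolution of the rubric.
#'
#' @param rubric A [domain_rubric()].
#' @param target_score Desired score in \[0, 10\].
#' @return `data.frame` with `keyword_id` and `present` (rubric order), with
#'   attribute `realized` holding the achieved score.
#' @export
#' @examples
#' r <- domain_rubric("P1", "outcomes", data.frame(
#'   id = letters[1:4], text = LETTERS[1:4], weight = c(4, 3, 2, 1)))
#' attr(realize_keywords(r, 5), "realized")  # 5: takes weights 4 and 1
realize_keywords <- function(rubric, target_score) {
  stopifnot(inherits(rubric, "domain_rubric"))
  if (!is.numeric(target_score) || length(target_score) != 1L ||
      is.na(target_score) || target_score < 0 || target_score > 10) {
    stop("`target_score` must be a number in [0, 10]", call. = FALSE)
  }
  w <- rubric$weight
  total <- sum(w)
  ord <- order(-w)              # ties keep rubric order (stable)
  present <- logical(length(w))
  cum <- 0
  for (i in ord) {
    contrib <- 10 * w[i] / total
    if (cum + contrib <= target_score + 1e-9) {
      present[i] <- TRUE
      cum <- cum + contrib
    }
  }
  structure(data.frame(keyword_id = rubric$id, present = present,
                       stringsAsFactors = FALSE),
            realized = 10 * sum(w[present]) / total)
}

#' Monte-Carlo power (or type-I error) of the primary analysis
#'
#' Generates `n_replicates` trials from `config`, analyzes each with
#' [primary_effect()], and reports the fraction of replicates with
#' \eqn{p < \alpha} together with its binomial Monte-Carlo standard error.
#' With `config$beta = 0` the result is the empirical type-I error.
#'
#' @param config A [simulation_config()]; `n_replicates` must be >= 100 and
#'   `seed` governs the whole run.
#' @param alpha Two-sided nominal level (default 0.05).
#' @return Object of class `power_sim`: `rejection_proportion`, `mc_se`,
#'   `n_replicates`, `alpha`, `beta`.
#' @export
simulate_power <- function(config, alpha = 0.05) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_replicates < 100L) {
    stop("need n_replicates >= 100 for a meaningful proportion",
         call. = FALSE)
  }
  stopifnot(alpha > 0, alpha <= 1)
  rep_cfg <- config
  rep_cfg$seed <- NULL          # replicates draw from the seeded stream
  rep_cfg$n_replicates <- 1L
  rej <- with_seed(config$seed, {
    vapply(seq_len(config$n_replicates), function(i) {
      primary_effect(generate_trial(rep_cfg)$scores)$p_value < alpha
    }, logical(1))
  })
  p <- mean(rej)
  structure(list(rejection_proportion = p,
                 mc_se = sqrt(p * (1 - p) / length(rej)),
                 n_replicates = length(rej), alpha = alpha,
                 beta = config$beta),
            class = "power_sim")
}

#' @export
print.power_sim <- function(x, ...) {
  cat(sprintf(
    "Rejection proportion %.4f (MC SE %.4f) over %d replicates at alpha = %g (beta = %g)\n",
    x$rejection_proportion, x$mc_se, x$n_replicates, x$alpha, x$beta))
  invisible(x)
}

#' Analytic power of the split-manuscript design
#'
#' The normal-approximation power consistent with the sample-size formula:
#' \deqn{\Phi\!\left(\frac{\Delta}{\sigma\sqrt{2\,IF/n}} -
#'       z_{1-\alpha/2}\right)}
#' with `n` domain-level observations per group and the design-effect
#' inflation factor `IF` of [inflation_factor()].
#'
#' @param params A [design_params()].
#' @param n_per_group Domain-level observations per group (>= 1).
#' @return Power in (0, 1).
#' @export
#' @examples
#' analytic_power(design_params(), 120)  # about 0.905
analytic_power <- function(params, n_per_group) {
  stopifnot(inherits(params, "design_params"), n_per_group >= 1)
  ifac <- inflation_factor(params)
  se <- params$sigma * sqrt(2 * ifac / n_per_group)
  stats::pnorm(params$delta / se - stats::qnorm(1 - params$alpha / 2))
}

#' Sensitivity of the primary effect to the keyword weighting system
#'
#' The completeness score depends on pre-specified keyword weights. This
#' simulation redraws all weights from a declared scheme, rescores every
#' domain from the fixed keyword-level consensus, re-estimates the primary
#' effect, and summarizes the distribution of \eqn{\hat\beta} across
#' replicates. Schemes: `"uniform_integer"` draws each weight uniformly from
#' 1..5; `"dirichlet"` draws each domain's weight vector from a symmetric
#' Dirichlet(1) scaled by the number of keywords; `"identity"` keeps the
#' original weights (degenerate reference).
#'
#' @param consensus Keyword-level consensus records covering every rubric
#'   keyword for every protocol in `allocation`.
#' @param rubrics Named list of [protocol_rubric()] objects keyed by
#'   protocol id, or a single protocol rubric shared by all protocols.
#' @param allocation `data.frame` with columns `participant_id` (or
#'   `participant_index`), `protocol_id`, `domain`, `condition` linking each
#'   scored domain to its condition.
#' @param scheme Weighting scheme name.
#' @param n_replicates Number of weight redraws (default 200).
#' @param seed RNG seed.
#' @return Object of class `weight_sensitivity`: original `beta_hat`, the
#'   replicate values `beta_replicates`, their quantiles (2.5, 25, 50, 75,
#'   97.5\%), `min`, `max`, `scheme`, `n_replicates`.
#' @export
weight_sensitivity <- function(consensus, rubrics, allocation,
                               scheme = c("uniform_integer", "dirichlet",
                                          "identity"),
                               n_replicates = 200L, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_replicates >= 1)
  alloc <- as.data.frame(allocation, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(alloc)) {
    if (!"participant_index" %in% names(alloc)) {
      stop("allocation needs participant_id or participant_index",
           call. = FALSE)
    }
    alloc$participant_id <- sprintf("S%03d", alloc$participant_index)
  }
  pids <- unique(alloc$protocol_id)
  if (inherits(rubrics, "protocol_rubric")) {
    shared <- rubrics
    rubrics <- lapply(pids, function(p) rekey_rubric(shared, p))
    names(rubrics) <- pids
  }
  missing_r <- setdiff(pids, names(rubrics))
  if (length(missing_r)) {
    stop("no rubric for protocol(s): ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  }

  score_with <- function(rubs) {
    sc <- score_consensus(rubs, consensus)
    idx <- match(paste(alloc$protocol_id, alloc$domain, sep = "\r"),
                 paste(sc$protocol_id, sc$domain, sep = "\r"))
    if (anyNA(idx)) stop("consensus does not cover the allocation",
                         call. = FALSE)
    as_score_table(data.frame(
      participant_id = alloc$participant_id,
      protocol_id = alloc$protocol_id, domain = alloc$domain,
      condition = alloc$condition, score = sc$score[idx],
      stringsAsFactors = FALSE))
  }
  beta0 <- primary_effect(score_with(rubrics[pids]))$beta_hat

  redraw <- function(rub) {
    doms <- lapply(unname(rub), function(d) {
      k <- nrow(d)
      d$weight <- switch(scheme,
        uniform_integer = sample(5L, k, replace = TRUE),
        dirichlet = { g <- stats::rgamma(k, 1); k * g / sum(g) },
        identity = d$weight)
      domain_rubric(attr(d, "protocol_id"), attr(d, "domain"),
                    as.data.frame(d))
    })
    protocol_rubric(attr(rub, "protocol_id"), doms)
  }
  betas <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      primary_effect(score_with(lapply(rubrics[pids], redraw)))$beta_hat
    }, numeric(1))
  })
  structure(list(beta_hat = beta0, beta_replicates = betas,
                 quantiles = stats::quantile(
                   betas, c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 min = min(betas), max = max(betas), scheme = scheme,
                 n_replicates = as.integer(n_replicates)),
            class = "weight_sensitivity")
}

# Copy a protocol rubric under a new protocol id (shared-rubric designs).
rekey_rubric <- function(rubric, protocol_id) {
  protocol_rubric(protocol_id, lapply(unname(rubric), function(d) {
    domain_rubric(protocol_id, attr(d, "domain"), as.data.frame(d))
  }))
}

#' @export
print.weight_sensitivity <- function(x, ...) {
  cat(sprintf(
    "Weight-sensitivity of beta_hat (%s scheme, %d replicates)\n",
    x$scheme, x$n_replicates))
  cat(sprintf("  original beta_hat: %.3f\n", x$beta_hat))
  q <- x$quantiles
  cat(sprintf("  quantiles: 2.5%% %.3f | 25%% %.3f | 50%% %.3f | 75%% %.3f | 97.5%% %.3f\n",
              q[1], q[2], q[3], q[4], q[5]))
  cat(sprintf("  range: %.3f to %.3f\n", x$min, x$max))
  invisible(x)
}
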