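#' Enumerate the 3-of-6 allocation patterns
#'
#' Each participant writes all six methods domains; an allocation pattern
#' assigns exactly three of them to the writing-aid condition, the
#' complement to usual writing. There are \eqn{\binom{6}{3} = 20} such
#' patterns, returned in deterministic lexicographic order over
#' [trial_domains()].
#'
#' @return List of 20 character vectors, each the three tool-condition
#'   domains of one pattern.
#' @export
#' @examples
#' length(enumerate_patterns())  # 20
enumerate_patterns <- function() {
  doms <- trial_domains()
  combs <- utils::combn(seq_along(doms), 3L)
  lapply(seq_len(ncol(combs)), function(j) doms[combs[, j]])
}

#' Permuted-block randomization over allocation patterns
#'
#' Generates the allocation sequence for `n_participants` using permuted
#' blocks of 20: within each complete block every one of the 20 patterns
#' occurs exactly once in random order, so any multiple-of-20 prefix assigns
#' each domain to the tool condition exactly half the time. The final block
#' is truncated to reach `n_participants`.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed RNG seed recorded in the output; `NULL` uses the ambient RNG
#'   stream and records no seed.
#' @return Long `data.frame` of class `allocation_sequence` with columns
#'   `participant_index, block_index, pattern_id, domain, condition` (six
#'   rows per participant) and attributes `seed` and `block_size`.
#' @export
#' @examples
#' alloc <- generate_sequence(41, seed = 20140429)
#' table(alloc$condition)
generate_sequence <- function(n_participants, seed = NULL) {
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      is.na(n_participants) || n_participants < 1 ||
      n_participants != round(n_participants)) {
    stop("`n_participants` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_participants)
  patterns <- enumerate_patterns()
  b <- length(patterns)  # block size 20
  n_blocks <- ceiling(n / b)
  order_ids <- with_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(i) sample.int(b)))
  })[seq_len(n)]
  block_index <- rep(seq_len(n_blocks), each = b)[seq_len(n)]
  doms <- trial_domains()
  in_tool <- t(vapply(patterns, function(p) doms %in% p, logical(6L)))
  out <- data.frame(
    participant_index = rep(seq_len(n), each = 6L),
    block_index = rep(block_index, each = 6L),
    pattern_id = rep(order_ids, each = 6L),
    domain = rep(doms, times = n),
    condition = ifelse(as.vector(t(in_tool[order_ids, , drop = FALSE])),
                       "tool", "control"),
    stringsAsFactors = FALSE)
  structure(out, seed = seed, block_size = b,
            class = c("allocation_sequence", "data.frame"))
}

#' Write an allocation sequence as CSV
#'
#' Columns `participant_index, protocol_id, domain, condition, block_index,
#' seed`; `protocol_id` is filled where the sequence carries a protocol
#' assignment (see [assign_protocols()]), empty otherwise.
#'
#' @param alloc An [generate_sequence()] result.
#' @param path CSV destination.
#' @export
write_allocation <- function(alloc, path) {
  stopifnot(inherits(alloc, "allocation_sequence"))
  out <- data.frame(participant_index = alloc$participant_index,
                    protocol_id = alloc$protocol_id %||%
                      rep(NA_character_, nrow(alloc)),
                    domain = alloc$domain, condition = alloc$condition,
                    block_index = alloc$block_index,
                    seed = attr(alloc, "seed") %||% NA,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign one distinct protocol per participant
#'
#' Each participant writes the methods section of one protocol; assignment
#' is a seeded permutation of the supplied protocol identifiers (no
#' stratification).
#'
#' @param alloc An [generate_sequence()] result.
#' @param protocol_ids Character vector of at least as many protocols as
#'   participants.
#' @param seed Optional seed for the permutation.
#' @return `alloc` with a `protocol_id` column added.
#' @export
assign_protocols <- function(alloc, protocol_ids, seed = NULL) {
  stopifnot(inherits(alloc, "allocation_sequence"))
  n <- max(alloc$participant_index)
  protocol_ids <- as.character(protocol_ids)
  if (length(protocol_ids) < n) {
    stop("need at least ", n, " protocol ids, got ", length(protocol_ids),
         call. = FALSE)
  }
  perm <- with_seed(seed, sample(protocol_ids, n))
  alloc$protocol_id <- perm[alloc$participant_index]
  alloc
}

#' Design parameters for the split-manuscript trial
#'
#' Bundles the quantities governing the sample-size calculation and the
#' simulations, with the correlation structure of the split-unit design:
#' `rho` is the intraclass correlation between two domain scores written by
#' the same participant under the same condition; `rho_prime` the
#' correlation between two of their scores under different conditions
#' (the study set it to half of `rho`); `m` the number of domains per
#' participant per condition.
#'
#' Defaults are the study's assumptions: two-sided 5\% type-I error, 90\%
#' power, minimal difference 2 score points, per-domain SD 4 (0-10 scale),
#' `rho` = 0.8, `rho_prime` = 0.4, `m` = 3.
#'
#' @param alpha Two-sided type-I error level, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param delta Minimal clinically relevant difference (score units, > 0).
#' @param sigma Per-domain score standard deviation (> 0).
#' @param rho Within-condition intraclass correlation.
#' @param rho_prime Cross-condition correlation, `0 <= rho_prime <= rho <= 1`.
#' @param m Domains per participant per condition (>= 1).
#' @return Object of class `design_params`.
#' @export
design_params <- function(alpha = 0.05, power = 0.90, delta = 2, sigma = 4,
                          rho = 0.8, rho_prime = 0.4, m = 3) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            delta > 0, sigma > 0, m >= 1, m == round(m))
  if (!(rho_prime >= 0 && rho_prime <= rho && rho <= 1)) {
    stop("need 0 <= rho_prime <= rho <= 1 (got rho = ", rho,
         ", rho_prime = ", rho_prime, ")", call. = FALSE)
  }
  p <- structure(list(alpha = alpha, power = power, delta = delta,
                      sigma = sigma, rho = rho, rho_prime = rho_prime,
                      m = as.integer(m)),
                 class = "design_params")
  if (1 + (m - 1) * rho - m * rho_prime <= 0) {
    stop("degenerate design: inflation factor 1 + (m-1)*rho - m*rho' <= 0",
         call. = FALSE)
  }
  p
}

#' Design-effect inflation factor
#'
#' The variance inflation of the split-unit (cluster-crossover) design over
#' independent observations:
#' \deqn{IF = 1 + (m - 1)\rho - m\rho'}
#' With `rho_prime = 0` this is the classical cluster design effect
#' \eqn{1 + (m-1)\rho}; positive cross-condition correlation recovers
#' efficiency because each participant serves as their own control. At the
#' study values (m = 3, rho = 0.8, rho' = 0.4) it equals 1.4.
#'
#' @param params A [design_params()] object.
#' @return Numeric inflation factor (> 0).
#' @export
#' @examples
#' inflation_factor(design_params(m = 3, rho = 0.8, rho_prime = 0.4))  # 1.4
inflation_factor <- function(params) {
  stopifnot(inherits(params, "design_params"))
  ifac <- 1 + (params$m - 1) * params$rho - params$m * params$rho_prime
  if (ifac <= 0) stop("degenerate design: inflation factor <= 0",
                      call. = FALSE)
  ifac
}

#' Cluster-crossover sample size
#'
#' Two-stage calculation: the unrounded per-group requirement for
#' independent observations,
#' \deqn{n_0 = 2 (z_{1-\alpha/2} + z_{power})^2 \sigma^2 / \Delta^2,}
#' is multiplied by the inflation factor and rounded up to the nearest
#' multiple of `m` so that it converts to a whole number of participants
#' (`participants = domains_per_group / m`). At the study's assumptions this
#' yields 120 domains per group and 40 participants.
#'
#' @param params A [design_params()] object.
#' @return Object of class `sample_size`: list with `n0` (unrounded
#'   independent-observations requirement per group), `inflation_factor`,
#'   `n_inflated` (unrounded inflated requirement), `domains_per_group`,
#'   `participants`.
#' @export
#' @examples
#' required_sample_size(design_params())
required_sample_size <- function(params) {
  stopifnot(inherits(params, "design_params"))
  z <- stats::qnorm(1 - params$alpha / 2) + stats::qnorm(params$power)
  n0 <- 2 * z^2 * params$sigma^2 / params$delta^2
  ifac <- inflation_factor(params)
  n_inflated <- ifac * n0
  m <- params$m
  domains_per_group <- as.integer(m * ceiling(n_inflated / m))
  structure(list(n0 = n0, inflation_factor = ifac, n_inflated = n_inflated,
                 domains_per_group = domains_per_group,
                 participants = as.integer(domains_per_group / m),
                 params = params),
            class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  cat("Cluster-crossover sample size\n")
  cat(sprintf("  unrounded n per group (independent): %.2f\n", x$n0))
  cat(sprintf("  inflation factor:                    %.3f\n",
              x$inflation_factor))
  cat(sprintf("  inflated unrounded n per group:      %.2f\n", x$n_inflated))
  cat(sprintf("  domains per group:                   %d\n",
              x$domains_per_group))
  cat(sprintf("  participants:                        %d\n", x$participants))
  invisible(x)
}
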