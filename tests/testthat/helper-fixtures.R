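# Fixtures built in code: rubrics, consensus records, and hand-laid score
# tables with explicit allocation patterns.

make_keywords <- function(k, weights = NULL, essential = NULL,
                          prefix = "kw") {
  data.frame(id = paste0(prefix, seq_len(k)),
             text = paste("phrase", prefix, seq_len(k)),
             weight = weights %||% rep(1, k),
             essential = essential %||% rep(FALSE, k),
             stringsAsFactors = FALSE)
}

make_protocol_rubric <- function(protocol_id = "P1", k = 4,
                                 weights = NULL, essential = NULL) {
  protocol_rubric(protocol_id, lapply(trial_domains(), function(d) {
    domain_rubric(protocol_id, d,
                  make_keywords(k, weights, essential, prefix = paste0(d, "_")))
  }))
}

# Consensus covering a domain rubric with a given credited indicator.
make_consensus <- function(rubric, present,
                           flagged = rep(FALSE, nrow(rubric))) {
  data.frame(protocol_id = attr(rubric, "protocol_id"),
             domain = attr(rubric, "domain"),
             keyword_id = rubric$id, present = present,
             flagged_missing = flagged, resolved = FALSE,
             stringsAsFactors = FALSE)
}

# A random rubric for property tests (domain fixed, weights positive reals
# or integers).
random_rubric <- function(k = sample(1:12, 1), integer_weights = FALSE) {
  w <- if (integer_weights) sample(1:9, k, replace = TRUE)
       else stats::runif(k, 0.05, 8)
  domain_rubric("PR", sample(trial_domains(), 1),
                make_keywords(k, weights = w,
                              essential = sample(c(TRUE, FALSE), k,
                                                 replace = TRUE)))
}

# Build a balanced score table from an explicit list of tool-domain
# patterns (one character(3) per participant) and a score function or
# matrix. `scores` is a named-by-domain numeric vector per participant,
# supplied as a list.
make_score_table <- function(patterns, scores) {
  stopifnot(length(patterns) == length(scores))
  rows <- lapply(seq_along(patterns), function(p) {
    data.frame(participant_id = sprintf("S%02d", p),
               protocol_id = sprintf("P%02d", p),
               domain = trial_domains(),
               condition = ifelse(trial_domains() %in% patterns[[p]],
                                  "tool", "control"),
               score = unname(scores[[p]][trial_domains()]),
               stringsAsFactors = FALSE)
  })
  as_score_table(do.call(rbind, rows))
}

# Participant with given per-condition means and no within-condition
# spread: tool domains all get mean_tool, control all mean_control.
flat_scores <- function(pattern, mean_tool, mean_control) {
  s <- stats::setNames(rep(mean_control, 6), trial_domains())
  s[pattern] <- mean_tool
  s
}

pattern_a <- c("trial_design", "randomization", "blinding")
pattern_b <- c("participants", "interventions", "outcomes")

# Re-key a shared protocol rubric under another protocol id.
rekey_rubric_for_test <- function(rubric, protocol_id) {
  protocol_rubric(protocol_id, lapply(unname(rubric), function(d) {
    domain_rubric(protocol_id, attr(d, "domain"), as.data.frame(d))
  }))
}
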