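# Shared fixtures and independent oracles. Everything here is built in code
# at test time; the oracles are deliberately written with different machinery
# (lm(), power-set filters, covariance identities) than the implementation
# they check.

toy_bank <- function() {
  item_bank(data.frame(
    item_id = c("R1", "R2", "R3", "N1"),
    part = c("reading", "reading", "reading", "numeracy"),
    position = c(1L, 2L, 3L, 1L),
    set_id = c("S1", "S1", "S2", NA)
  ), name = "toy")
}

# Recovery instance: 10 reading items in 5 sets of 2. The two middle sets
# (s2, s3) carry all the discrimination; the outer sets are nearly
# deterministic (extreme difficulties, near-zero discrimination), so the
# full-length score is driven by the planted items.
recovery_bank <- function() {
  item_bank(data.frame(
    item_id = paste0("A", 1:10), part = "reading", position = 1:10,
    set_id = rep(c("s1", "s2", "s3", "s4", "s5"), each = 2)
  ), name = "recovery toy")
}

recovery_difficulties <- function() {
  stats::setNames(c(-40, -40, -0.6, -0.2, 0.2, 0.6, 40, 40, 40, 40),
                  paste0("A", 1:10))
}

recovery_config <- function(seed, n = 120) {
  cohort_config(recovery_bank(), n_participants = n, theta_mean = 0,
                theta_sd = 1.3, seed = seed,
                difficulties = recovery_difficulties(),
                planted_sets = c("s2", "s3"),
                planted_discrimination = 1.4,
                background_discrimination = 0.1)
}

recovery_cohort <- function(seed, n = 120) {
  bank <- recovery_bank()
  cohort <- simulate_cohort(bank, recovery_config(seed, n))
  list(bank = bank, sets = group_items(bank),
       responses = cohort$responses, theta = cohort$theta,
       full = score_full(cohort$responses, bank))
}

# A deterministic binary matrix with varied column patterns (no RNG).
binary_design <- function(n, p) {
  m <- outer(seq_len(n), seq_len(p), function(i, j) (i * j + i %/% (j + 1)) %% 2)
  colnames(m) <- paste0("x", seq_len(p))
  m
}

# --- independent oracles -----------------------------------------------

# LOOCV with lm(): separately coded route used to check loocv_evaluate()
# and as the evaluation engine of the naive search oracle.
oracle_loocv <- function(X, y, integer_trim = TRUE) {
  n <- nrow(X)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    df <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    fit <- lm(y ~ ., data = df)
    beta <- coef(fit)
    beta[is.na(beta)] <- 0  # lm drops aliased columns; treat as 0
    if (integer_trim) beta <- sign(beta) * floor(abs(beta) + 0.5)
    preds[i] <- beta[1] + sum(beta[-1] * X[i, ])
  }
  r <- if (sd(preds) > 0) cor(preds, y) else NA_real_
  list(predictions = preds, rmse = sqrt(mean((preds - y)^2)), r = r)
}

# Naive exhaustive search: enumerate the full power set of sets, bucket by
# total item count, evaluate each subset with oracle_loocv, and pick the
# winner per count under the same tie rules (r, then rmse, then fewer sets,
# then lexicographic ids).
oracle_search <- function(sets, responses, y, r_min = 0.9) {
  ids <- sort(names(sets), method = "radix")
  subsets <- unlist(lapply(seq_along(ids), function(k) {
    combn(ids, k, simplify = FALSE)
  }), recursive = FALSE)
  by_count <- split(subsets, vapply(subsets, function(s) sum(lengths(sets[s])),
                                    numeric(1)))
  winners <- list()
  for (count in sort(as.numeric(names(by_count)))) {
    if (count > nrow(responses) - 2) break
    best <- NULL
    for (s in by_count[[as.character(count)]]) {
      X <- responses[, unlist(sets[s]), drop = FALSE]
      ev <- oracle_loocv(X, y)
      cand <- list(sets = s, r = ev$r, rmse = ev$rmse)
      if (is.null(best)) { best <- cand; next }
      ra <- if (is.na(cand$r)) -Inf else cand$r
      rb <- if (is.na(best$r)) -Inf else best$r
      take <- if (ra != rb) ra > rb else if (cand$rmse != best$rmse) {
        cand$rmse < best$rmse
      } else if (length(cand$sets) != length(best$sets)) {
        length(cand$sets) < length(best$sets)
      } else paste(cand$sets, collapse = "|") < paste(best$sets, collapse = "|")
      if (take) best <- cand
    }
    winners[[as.character(count)]] <- best
    if (!is.na(best$r) && best$r >= r_min) break
  }
  winners
}
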