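# Independent oracles and label-construction helpers shared by the tests.

# Brute-force Cohen's kappa: expand the 2x2 table into its N paired labels,
# take observed agreement directly, and compute chance agreement by explicit
# enumeration of all N^2 rater pairings. Deliberately independent of the
# package's closed-form implementation.
kappa_bruteforce <- function(t) {
  ref <- rep(c(TRUE, TRUE, FALSE, FALSE), c(t$tp, t$fn, t$fp, t$tn))
  tst <- rep(c(TRUE, FALSE, TRUE, FALSE), c(t$tp, t$fn, t$fp, t$tn))
  p_o <- mean(ref == tst)
  p_e <- mean(outer(ref, tst, `==`))
  if (p_e == 1) return(if (p_o == 1) 1 else NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# Build overall-comparison label maps realizing given 2x2 cell counts.
labels_from_cells <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  ids <- sprintf("S%04d", seq_len(n))
  ref <- rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fn, fp, tn))
  tst <- rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fn, fp, tn))
  empty <- logical(n)
  list(
    reference = data.frame(participant_id = ids, overall = ref, SE = empty,
                           OE = empty, DE = empty, stringsAsFactors = FALSE),
    test = data.frame(participant_id = ids, overall = tst, SE = empty,
                      OE = empty, DE = empty, nos = empty,
                      stringsAsFactors = FALSE))
}

random_table <- function(max_n = 20L) {
  n <- sample(seq_len(max_n), 1L)
  p <- as.vector(stats::rmultinom(1L, n, prob = stats::runif(4)))
  contingency_table(tp = p[1], fp = p[2], fn = p[3], tn = p[4])
}

write_fixture_csvs <- function(fx, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  s <- file.path(dir, "surgical.csv")
  c <- file.path(dir, "claims.csv")
  write_surgical_table(fx$surgical, s)
  write_claims_table(fx$claims, c)
  list(surgical = s, claims = c, dir = dir)
}
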