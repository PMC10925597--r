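# Small cohort fixtures built in code.

table_schema_of <- function(tab) liquidcascade:::table_schema(tab)

# Tiny two-class table with named biomarkers; values strictly positive.
tiny_table <- function(n = 20, seed = 42) {
  set.seed(seed)
  v <- cbind(`CA-125` = rexp(n, 1), CEA = rexp(n, 1), AFP = rexp(n, 1))
  feature_table(v, rep(c("Cancer", "Normal"), length.out = n),
                feature_meta(colnames(v), routine = c(TRUE, TRUE, TRUE)))
}

# The parameter-recovery study conditions: 1000/1000 cohort, 40 generic
# biomarkers, 5 informative at a 2-SD log-scale effect, 3 redundant
# correlated pairs whose second member carries no effect.
recovery_config <- function(seed) {
  panel <- feature_meta(sprintf("B%02d", 1:40), unit = "pg/ml")
  cohort_config(
    n_per_class = c(Normal = 1000, Cancer = 1000),
    biomarkers = panel,
    informative = list(Cancer = c(B01 = 2, B02 = 2, B03 = 2, B04 = 2,
                                  B05 = 2)),
    correlated_pairs = list(list(a = "B01", b = "B06", rho = 0.85),
                            list(a = "B02", b = "B07", rho = 0.85),
                            list(a = "B03", b = "B08", rho = 0.85)),
    omega_shift = c(Normal = 0, Cancer = 1),
    seed = seed)
}

# Linearly separable binary table (one decisive feature).
separable_table <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("Cancer", "Normal"), each = n_per_class)
  # exactly two key levels: the histogram split lands between them, so
  # held-out samples can never straddle the learned threshold
  key <- ifelse(lab == "Cancer", 10, 1)
  v <- cbind(KEY = key, NOISE1 = rexp(n), NOISE2 = rexp(n))
  feature_table(v, lab)
}
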