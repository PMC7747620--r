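# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and the survival package, except where a test
# explicitly cross-checks against it).

# Naive Efron partial log-likelihood for a binary covariate, written as the
# direct per-event-time double loop.
oracle_cox_loglik <- function(beta, time, event, z) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    risk <- which(time >= t)
    dead <- which(time == t & event == 1)
    d <- length(dead)
    s0 <- sum(exp(beta * z[risk]))
    ed0 <- sum(exp(beta * z[dead]))
    ll <- ll + beta * sum(z[dead])
    for (l in seq_len(d) - 1) ll <- ll - log(s0 - (l / d) * ed0)
  }
  ll
}

# 1-D grid maximization of the partial likelihood: coarse pass then a fine
# pass at step 1e-4 around the coarse maximum.
oracle_cox_grid <- function(time, event, z, lim = 5) {
  coarse <- seq(-lim, lim, by = 0.01)
  ll <- vapply(coarse, oracle_cox_loglik, 0, time = time, event = event,
               z = z)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  llf <- vapply(fine, oracle_cox_loglik, 0, time = time, event = event,
                z = z)
  fine[which.max(llf)]
}

# Kendall tau-b by exhaustive pair enumeration with tie corrections.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Upper-tail hypergeometric p by exhaustive enumeration of all C(N, n)
# draws of the query from the universe (N <= 12 or so).
oracle_hypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K universe elements are "in the set"
  mean(hits >= k)
}

# Permutation log-rank p: proportion of label permutations whose chi2 is at
# least the observed one.
oracle_perm_logrank <- function(time, event, group, B = 2000, seed = 42) {
  set.seed(seed)
  obs <- logrank_test(time, event, group)$chi2
  hits <- 0
  for (b in seq_len(B)) {
    chi <- logrank_test(time, event, sample(group))$chi2
    if (chi >= obs - 1e-12) hits <- hits + 1
  }
  hits / B
}

# Small-cohort generators for the survival tests.
random_survival_data <- function(n = 40, tie_prob = 0.5, seed = 1) {
  set.seed(seed)
  time <- if (stats::runif(1) < tie_prob) sample(1:12, n, replace = TRUE)
          else round(stats::rexp(n, 1 / 10), 4)
  event <- stats::rbinom(n, 1, 0.6)
  if (sum(event) == 0) event[1] <- 1
  z <- sample(c(1, 0), n, replace = TRUE)
  g <- factor(ifelse(z == 1, "high", "low"), levels = c("high", "low"))
  list(time = time, event = event, z = z, group = g)
}

tiny_expression <- function() {
  matrix(c(5, 1, 3, 4,
           2, 8, 6, 7,
           1, 1, 2, 9),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("miR-a", "miR-b", "miR-c"),
                         c("s1", "s2", "s3", "s4")))
}

tiny_clinical <- function() {
  data.frame(sample_id = c("s1", "s2", "s3", "s4"),
             time = c(100, 200, 300, 400), event = c(1, 1, 0, 1),
             stringsAsFactors = FALSE)
}

# The four published synergistic-pair summaries shipped with the package.
published_pairs <- function() {
  read.delim(system.file("extdata", "cesc_synergy_pairs.tsv",
                         package = "mircombo"))
}

published_clinical_counts <- function() {
  read.delim(system.file("extdata", "cesc_clinical_counts.tsv",
                         package = "mircombo"))
}

# Expand a counts table into a per-patient clinical data.frame (times and
# events are placeholders; only the categorical columns matter).
expand_counts <- function(counts, variable) {
  rows <- counts[counts$variable == variable, ]
  cat <- rep(rows$category, rows$n)
  cat[cat == "N/A"] <- NA
  n <- length(cat)
  df <- data.frame(sample_id = sprintf("p%03d", seq_len(n)),
                   time = rep(100, n), event = rep(0L, n),
                   stringsAsFactors = FALSE)
  df[[variable]] <- cat
  df
}
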