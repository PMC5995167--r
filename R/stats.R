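# Sequential orthonormal bases for the model terms: each term's model-matrix
# columns are residualised against everything before it (twice, for
# numerical stability) and orthonormalised; projections onto these blocks
# give type-I (sequential) sums of squares cheaply for thousands of
# permuted responses at once.
term_projections <- function(data, terms) {
  n <- nrow(data)
  Qall <- matrix(1 / sqrt(n), n, 1L) # intercept
  blocks <- list()
  for (tm in terms) {
    X <- stats::model.matrix(stats::as.formula(paste("~", tm)), data = data)
    X <- X[, -1L, drop = FALSE]
    for (pass in 1:2) X <- X - Qall %*% crossprod(Qall, X)
    qrX <- qr(X)
    r <- qrX$rank
    if (r == 0L) {
      blocks[[tm]] <- NULL
      next
    }
    Qj <- qr.Q(qrX)[, seq_len(r), drop = FALSE]
    blocks[[tm]] <- Qj
    Qall <- cbind(Qall, Qj)
  }
  list(blocks = blocks, Qall = Qall, n = n)
}

#' Permutation ANOVA over a long gene table
#'
#' Tests a per-gene, per-species response against the factors `gene`,
#' `pair`, `mode` and the `pair:mode` interaction (order configurable)
#' using sequential (type-I) sums of squares. Each factor's observed F
#' statistic is compared with its null distribution obtained by permuting
#' the raw response values `B` times and recomputing all F statistics, so
#' `p = (1 + #\{F* >= F_obs\}) / (B + 1)`. A Freedman--Lane variant
#' (permuting residuals of the model without the tested term) is available.
#' Factors with a single level are skipped with a warning.
#'
#' @param data Long tibble with one response per (gene, species); must
#'   contain the columns named in `terms` and `response`.
#' @param response Response column name (string).
#' @param terms Model terms in testing order.
#' @param B Number of permutations (default 5000).
#' @param seed Seed for the permutation stream.
#' @param scheme `"raw"` (unrestricted permutation of responses) or
#'   `"freedman_lane"`.
#' @return An object of class `perm_anova`: a tibble with one row per term
#'   (`term`, `df`, `ss`, `statistic`, `p_value`) plus attributes recording
#'   `B`, `seed`, `scheme`, the response name and `n`.
#' @export
permutation_anova <- function(data, response,
                              terms = c("gene", "pair", "mode", "pair:mode"),
                              B = 5000L, seed = 1L,
                              scheme = c("raw", "freedman_lane")) {
  scheme <- match.arg(scheme)
  data <- as_tibble(data)
  y <- data[[response]]
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 3L) abort("too few observations", class = "asexdiv_input")

  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in base_vars) data[[v]] <- factor(data[[v]])
  single <- vapply(base_vars, function(v) nlevels(data[[v]]) < 2L, TRUE)
  if (any(single)) {
    dropped <- base_vars[single]
    warn(paste0(
      "factor(s) with a single level skipped: ", paste(dropped, collapse = ", ")
    ))
    terms <- terms[!vapply(terms, function(tm) {
      any(strsplit(tm, ":", fixed = TRUE)[[1L]] %in% dropped)
    }, TRUE)]
  }
  if (length(terms) == 0L) abort("no testable terms", class = "asexdiv_input")

  proj <- term_projections(data, terms)
  terms <- names(proj$blocks)
  df_term <- vapply(proj$blocks, ncol, 0L)
  df_res <- n - 1L - sum(df_term)
  if (df_res <= 0L) abort("no residual degrees of freedom", class = "asexdiv_input")

  ss_of <- function(Y) {
    # Y: n x m matrix of responses; returns list(ss = terms x m, sse = m)
    QtY <- crossprod(proj$Qall, Y)
    tot <- colSums(Y^2) - QtY[1L, ]^2
    idx <- 1L
    ss <- matrix(0, length(terms), ncol(Y))
    for (j in seq_along(terms)) {
      rows <- idx + seq_len(df_term[j])
      ss[j, ] <- colSums(QtY[rows, , drop = FALSE]^2)
      idx <- idx + df_term[j]
    }
    list(ss = ss, sse = tot - colSums(ss))
  }
  tol <- 1e-9 * (sum(y * y) + 1)
  f_stat <- function(ss, sse) {
    # numerically-zero SS counts as zero, so a constant response yields
    # F = 0 everywhere (and p = 1); a perfect fit with signal yields Inf
    out <- (ss / df_term) / rep(pmax(sse, 0) / df_res, each = length(df_term))
    out[ss <= tol] <- 0
    out[ss > tol & rep(sse, each = length(df_term)) <= tol] <- Inf
    out
  }
  obs <- ss_of(matrix(y, n, 1L))
  F_obs <- f_stat(obs$ss, obs$sse)[, 1L]

  exceed <- rep(0L, length(terms))
  withr::with_seed(seed, {
    if (scheme == "raw") {
      chunk <- 500L
      done <- 0L
      while (done < B) {
        m <- min(chunk, B - done)
        Y <- vapply(seq_len(m), function(i) y[sample.int(n)], numeric(n))
        perm <- ss_of(Y)
        Fp <- f_stat(perm$ss, perm$sse)
        exceed <- exceed + rowSums(Fp >= F_obs - 1e-12)
        done <- done + m
      }
    } else {
      # Freedman-Lane: for each term, permute residuals of the model
      # excluding that term's block, add back its fitted values
      for (j in seq_along(terms)) {
        Qred <- do.call(cbind, c(
          list(proj$Qall[, 1L, drop = FALSE]),
          proj$blocks[-j]
        ))
        fit <- Qred %*% crossprod(Qred, y)
        res <- y - fit
        for (b in seq_len(B)) {
          ystar <- fit + res[sample.int(n)]
          perm <- ss_of(matrix(ystar, n, 1L))
          Fp <- f_stat(perm$ss, perm$sse)[j, 1L]
          if (Fp >= F_obs[j] - 1e-12) exceed[j] <- exceed[j] + 1L
        }
      }
    }
  })
  out <- tibble(
    term = terms, df = df_term, ss = obs$ss[, 1L],
    statistic = F_obs, p_value = (1 + exceed) / (B + 1)
  )
  structure(out,
    class = c("perm_anova", class(out)),
    B = B, seed = seed, scheme = scheme, response = response, n = n,
    df_residual = df_res
  )
}

#' @method tidy perm_anova
#' @export
tidy.perm_anova <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @method glance perm_anova
#' @export
glance.perm_anova <- function(x, ...) {
  tibble(
    response = attr(x, "response"), n = attr(x, "n"), B = attr(x, "B"),
    seed = attr(x, "seed"), scheme = attr(x, "scheme"),
    df_residual = attr(x, "df_residual")
  )
}

#' Paired tests of per-pair sexual vs asexual summaries
#'
#' Two-sided paired t test (df = n - 1) and Wilcoxon signed-rank test on
#' per-pair (sexual, asexual) summary values.
#'
#' @param data Tibble with columns `pair_id`, `sexual`, `asexual`, or a
#'   long tibble with columns `pair_id`, `mode`, `value`.
#' @return One-row tibble: `n`, `mean_diff` (sexual - asexual),
#'   `statistic` (t), `df`, `p_value`, `wilcoxon_p`.
#' @export
paired_tests <- function(data) {
  data <- as_tibble(data)
  if (all(c("mode", "value") %in% names(data))) {
    data <- tidyr::pivot_wider(
      data[, c("pair_id", "mode", "value")],
      names_from = "mode", values_from = "value"
    )
  }
  if (!all(c("sexual", "asexual") %in% names(data))) {
    abort("need sexual and asexual values per pair", class = "asexdiv_input")
  }
  d <- data$sexual - data$asexual
  d <- d[!is.na(d)]
  if (length(d) < 2L) abort("need at least 2 pairs", class = "asexdiv_input")
  if (stats::sd(d) == 0) {
    abort("zero variance of paired differences: t test degenerate",
      class = "asexdiv_degenerate"
    )
  }
  tt <- stats::t.test(d)
  wt <- suppressWarnings(stats::wilcox.test(d))
  tibble(
    n = length(d), mean_diff = mean(d),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, wilcoxon_p = wt$p.value
  )
}

#' Seeded percentile bootstrap confidence interval
#'
#' @param values Numeric vector (`n >= 2`).
#' @param statistic `"median"`, `"mean"`, or a function.
#' @param B Resamples.
#' @param level Confidence level.
#' @param seed Seed.
#' @return One-row tibble: `estimate`, `lower`, `upper`, `B`, `level`.
#' @export
bootstrap_ci <- function(values, statistic = c("median", "mean"),
                         B = 5000L, level = 0.95, seed = 1L) {
  if (length(values) < 2L) {
    abort("need at least two values to bootstrap", class = "asexdiv_input")
  }
  fn <- if (is.function(statistic)) {
    statistic
  } else {
    switch(match.arg(statistic), median = stats::median, mean = mean)
  }
  est <- fn(values)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(B), function(i) fn(sample(values, replace = TRUE)), numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble(estimate = est, lower = qs[1L], upper = qs[2L], B = B, level = level)
}

#' Correlation between asexual lineage age and an effect size
#'
#' Pearson product-moment correlation (two-sided t test, df = n - 2)
#' between a per-pair effect size and a per-pair age proxy such as the
#' Jukes--Cantor divergence or its rank. With the typical five pairs the
#' test has very little power and any correlation can be driven by a single
#' old lineage, so a warning is attached for `n <= 5`.
#'
#' @param data Tibble with columns `effect` and `age` (one row per pair).
#' @return One-row tibble: `n`, `r`, `statistic` (t), `df`, `p_value`.
#' @export
age_correlation <- function(data) {
  data <- as_tibble(data)
  d <- data[is.finite(data$effect) & is.finite(data$age), , drop = FALSE]
  if (nrow(d) < 3L) abort("need at least 3 pairs", class = "asexdiv_input")
  if (stats::var(d$effect) == 0 || stats::var(d$age) == 0) {
    abort("zero variance: correlation undefined", class = "asexdiv_degenerate")
  }
  if (nrow(d) <= 5L) {
    warn("correlation based on <= 5 pairs: interpret with caution")
  }
  ct <- stats::cor.test(d$effect, d$age, method = "pearson")
  tibble(
    n = nrow(d), r = unname(ct$estimate), statistic = unname(ct$statistic),
    df = unname(ct$parameter), p_value = ct$p.value
  )
}
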