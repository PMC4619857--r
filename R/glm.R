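#' Fit the same linear model at every mesh vertex
#'
#' The shared least-squares engine behind all the covariance maps: ordinary
#' least squares of each column of `Y` on the design `X`, with the t
#' statistic for one named column computed from the vertex residual
#' variance and the design covariance \eqn{(X'X)^{-1}}. Per-vertex
#' residuals are retained for the residual-based smoothness estimate that
#' random-field correction needs.
#'
#' Vertices with (numerically) zero residual variance get a flagged
#' infinite t of the coefficient's sign (0 if the coefficient is 0); they
#' are excluded from smoothness estimation downstream but kept in
#' thresholding.
#'
#' @param Y numeric matrix, subjects x vertices.
#' @param X design matrix with column names; an intercept column is
#'   expected (use [design_matrix()]).
#' @param contrast name of the column whose coefficient is tested.
#' @return object of class `statmap`: per-vertex `beta` (units of mm per
#'   unit regressor), `se`, `t`, scalar residual `df = n - rank(X)`,
#'   logical `flagged` (zero residual variance), the `residuals` matrix,
#'   plus `contrast`, `terms` and `n`.
#' @export
fit_vertexwise <- function(Y, X, contrast) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("'X' must have column names")
  if (nrow(Y) != nrow(X)) stop("Y and X disagree on the number of subjects")
  if (!contrast %in% colnames(X))
    stop("contrast '", contrast, "' is not a design column")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  n <- nrow(X)
  df <- n - qx$rank
  if (df <= 0) stop("no residual degrees of freedom (n <= rank)")
  beta_all <- qr.coef(qx, Y)
  res <- Y - X %*% beta_all
  rss <- colSums(res^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  cc <- which(colnames(X) == contrast)
  beta <- beta_all[cc, ]
  se <- sqrt(sigma2 * XtXinv[cc, cc])
  scale <- mean(colSums(Y^2)) + 1
  flagged <- sigma2 < 1e-24 * scale
  tval <- beta / se
  tval[flagged] <- sign(beta[flagged]) * Inf
  tval[flagged & abs(beta) < 1e-12] <- 0
  structure(list(beta = unname(beta), se = unname(se), t = unname(tval),
                 df = df, flagged = unname(flagged),
                 residuals = unname(res), contrast = contrast,
                 terms = colnames(X), n = n),
            class = "statmap")
}

#' @export
print.statmap <- function(x, ...) {
  cat("statmap: contrast '", x$contrast, "' over ", length(x$t),
      " vertices\n", sep = "")
  cat("  model terms: ", paste(x$terms, collapse = " + "),
      "  (n = ", x$n, ", residual df = ", x$df, ")\n", sep = "")
  tf <- x$t[is.finite(x$t)]
  cat("  t range [", format(min(tf), digits = 4), ", ",
      format(max(tf), digits = 4), "]",
      if (any(x$flagged)) paste0(", ", sum(x$flagged), " degenerate vertices"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.statmap <- function(object, p = 0.05, ...) {
  pos <- uncorrected_mask(object, p, "positive")
  neg <- uncorrected_mask(object, p, "negative")
  out <- list(contrast = object$contrast, n = object$n, df = object$df,
              n_vertices = length(object$t),
              n_flagged = sum(object$flagged),
              trend_p = p, n_positive = sum(pos), n_negative = sum(neg))
  class(out) <- "summary.statmap"
  out
}

#' @export
print.summary.statmap <- function(x, ...) {
  cat("Vertex-wise model, contrast '", x$contrast, "': n = ", x$n,
      ", df = ", x$df, ", ", x$n_vertices, " vertices\n", sep = "")
  cat("  uncorrected p < ", x$trend_p, ": ", x$n_positive, " positive, ",
      x$n_negative, " negative", sep = "")
  if (x$n_flagged) cat("  (", x$n_flagged, " degenerate)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.statmap <- function(x, p = 0.05, ...) {
  tf <- x$t[is.finite(x$t)]
  graphics::hist(tf, breaks = 50, main = paste0("t field: ", x$contrast),
                 xlab = paste0("t (df = ", x$df, ")"), ...)
  thr <- stats::qt(1 - p, x$df)
  graphics::abline(v = c(-thr, thr), lty = 2)
  invisible(x)
}

#' @export
coef.statmap <- function(object, ...) object$beta

#' @export
residuals.statmap <- function(object, ...) object$residuals

#' @export
as.data.frame.statmap <- function(x, ...) {
  data.frame(vertex_index = seq_along(x$t) - 1L, beta = x$beta, t = x$t,
             df = x$df)
}

#' Build a named design matrix with an intercept
#'
#' @param ... named numeric vectors (regressors), one value per subject.
#' @return numeric matrix with an `(Intercept)` column prepended.
#' @export
design_matrix <- function(...) {
  cols <- list(...)
  if (is.null(names(cols)) || any(names(cols) == ""))
    stop("all design columns must be named")
  n <- length(cols[[1]])
  X <- cbind(`(Intercept)` = rep(1, n), do.call(cbind, cols))
  X
}

#' Remove age and sex effects from every vertex
#'
#' Per-vertex OLS of thickness on [1, age, sex]; the residuals replace the
#' raw measurements before any covariance model is fitted, so downstream
#' seed means and maps are covariate-adjusted. Residuals are mean-zero and
#' orthogonal to both covariates; the projection is idempotent.
#'
#' @param Y subjects x vertices matrix.
#' @param covariates data.frame (or list) with numeric `age` and `sex`.
#' @return adjusted matrix, same shape as `Y`.
#' @export
residualize_covariates <- function(Y, covariates) {
  age <- covariates$age
  sex <- covariates$sex
  if (anyNA(age) || anyNA(sex)) stop("covariates must have no missing values")
  for (nm in c("age", "sex"))
    if (stats::var(covariates[[nm]]) == 0)
      stop("covariate '", nm, "' is constant; design would be collinear")
  X <- design_matrix(age = age, sex = sex)
  qx <- qr(X)
  as.matrix(Y) - X %*% qr.coef(qx, as.matrix(Y))
}

#' Mean adjusted thickness within a seed region
#'
#' Unweighted mean over the seed's vertices, one value per subject.
#'
#' @param Y subjects x vertices matrix (normally covariate-adjusted).
#' @param seed a [seed_region()].
#' @return numeric vector, one value per subject (mm, adjusted).
#' @export
seed_mean <- function(Y, seed) {
  if (!inherits(seed, "seed_region")) stop("'seed' must be a seed_region")
  idx <- seed$vertex_indices
  if (any(idx > ncol(Y))) stop("seed indices exceed the vertex count")
  rowMeans(as.matrix(Y)[, idx, drop = FALSE])
}

#' Per-group structural covariance map
#'
#' Simple regression of every vertex's adjusted thickness on the seed
#' value, within one group: T_i = b0 + b1 T_seed + e. The t field for b1
#' (df = n - 2) is the group's seed-based covariance network; significant
#' correlation is read as connectivity.
#'
#' @param Y adjusted thickness restricted to one group's rows.
#' @param seed_values per-subject seed means for the same rows.
#' @return a `statmap` for the `seed` term, with the per-vertex Pearson r
#'   attached as `$r`.
#' @export
scn_map <- function(Y, seed_values) {
  if (nrow(as.matrix(Y)) < 4) stop("need at least 4 subjects in the group")
  if (stats::var(seed_values) == 0)
    stop("degenerate seed: zero variance across subjects")
  sm <- fit_vertexwise(Y, design_matrix(seed = seed_values), "seed")
  r <- sm$t / sqrt(sm$t^2 + sm$df)
  r[sm$flagged] <- sign(sm$t[sm$flagged])
  sm$r <- r
  sm
}

#' Seed-by-moderator interaction map
#'
#' Fits T_i = b0 + b1 T_seed + b2 M + b3 T_seed*M + e at every vertex and
#' tests b3 (df = n - 4). With the group indicator (HC = 0 / PI = 1) as
#' moderator, b3 is exactly the PI-minus-HC difference of per-group
#' covariance slopes; with the PSQI score it is the parametric modulation
#' of covariance strength by sleep quality.
#'
#' @param Y adjusted thickness, all subjects.
#' @param seed_values per-subject seed means.
#' @param moderator numeric per-subject moderator (group indicator or PSQI
#'   score); must not be constant.
#' @param name moderator name used in the design ("group" or "psqi").
#' @return a `statmap` for the `seed:<name>` product term.
#' @export
interaction_map <- function(Y, seed_values, moderator, name = "group") {
  if (stats::var(moderator) == 0) stop("moderator is constant")
  X <- design_matrix(seed = seed_values, mod = moderator,
                     inter = seed_values * moderator)
  colnames(X) <- c("(Intercept)", "seed", name, paste0("seed:", name))
  fit_vertexwise(Y, X, paste0("seed:", name))
}

#' Vertex-wise thickness group comparison
#'
#' Group difference in raw thickness at every vertex, controlling for age,
#' sex and the global mean thickness (per-subject mean over all mesh
#' vertices). The group t is signed PI minus HC under 0/1 coding; with two
#' groups this t-test is identical to the one-way ANOVA F = t^2.
#'
#' @param Y raw thickness, subjects x vertices.
#' @param cohort data.frame with `group`, `age`, `sex`.
#' @return a `statmap` for the `group` term (df = n - 5).
#' @export
thickness_group_map <- function(Y, cohort) {
  Y <- as.matrix(Y)
  X <- design_matrix(group = cohort$group, age = cohort$age,
                     sex = cohort$sex, mean_ct = rowMeans(Y))
  fit_vertexwise(Y, X, "group")
}

#' Vertex-wise thickness-PSQI partial correlation map
#'
#' Association between thickness and the PSQI sleep-quality score removing
#' age, sex and global mean thickness: implemented as the t for the PSQI
#' term in [1, psqi, age, sex, meanCT], which is equivalent to the partial
#' Pearson correlation (reported as `$r`, r = t / sqrt(t^2 + df)).
#'
#' @param Y raw thickness, subjects x vertices.
#' @param cohort data.frame with `psqi`, `age`, `sex`.
#' @return a `statmap` for the `psqi` term with partial `$r` attached.
#' @export
thickness_psqi_map <- function(Y, cohort) {
  if (stats::var(cohort$psqi) == 0) stop("PSQI is constant across subjects")
  Y <- as.matrix(Y)
  X <- design_matrix(psqi = cohort$psqi, age = cohort$age,
                     sex = cohort$sex, mean_ct = rowMeans(Y))
  sm <- fit_vertexwise(Y, X, "psqi")
  r <- sm$t / sqrt(sm$t^2 + sm$df)
  r[sm$flagged] <- sign(sm$t[sm$flagged])
  sm$r <- r
  sm
}

#' Write and read statistic maps
#'
#' The TSV carries `vertex_index` (0-based), `beta`, `t`, `df`; a JSON
#' sidecar (same path with `.json`) records the contrast, model terms and
#' n. Optionally exports the t field as an ASCII GIFTI functional file.
#'
#' @param statmap a `statmap`.
#' @param path output TSV path.
#' @param gifti optional `.func.gii` path for the t field.
#' @export
write_statmap <- function(statmap, path, gifti = NULL) {
  write_tsv(as.data.frame(statmap), path)
  meta <- list(contrast = statmap$contrast, terms = statmap$terms,
               n = statmap$n, df = statmap$df,
               n_flagged = sum(statmap$flagged))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (!is.null(gifti)) write_gifti_func(statmap$t, gifti)
  invisible(path)
}

#' @rdname write_statmap
#' @export
read_statmap <- function(path) {
  df <- read_tsv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(beta = df$beta, se = NULL, t = df$t, df = df$df[1],
                 flagged = !is.finite(df$t), residuals = NULL,
                 contrast = meta$contrast, terms = meta$terms, n = meta$n),
            class = "statmap")
}

#' Two-sample t-test from summary statistics
#'
#' Closed-form test from per-group mean, sd and n, as used for
#' demographics tables. `variance = "pooled"` is the classical equal-
#' variance form (the default); `"welch"` uses the Satterthwaite
#' approximation. One-tailed p is for the alternative group1 > group2.
#'
#' @param m1,sd1,n1 summary statistics of group 1.
#' @param m2,sd2,n2 summary statistics of group 2.
#' @param tails 1 or 2.
#' @param variance "pooled" or "welch".
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(m1, sd1, n1, m2, sd2, n2, tails = 2,
                         variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  if (!tails %in% c(1, 2)) stop("'tails' must be 1 or 2")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (variance == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1; b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  tval <- (m1 - m2) / se
  p <- if (tails == 2) 2 * stats::pt(-abs(tval), df)
       else stats::pt(tval, df, lower.tail = FALSE)
  list(t = tval, df = df, p = p)
}

#' Pearson chi-square test of a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param a,b,c,d cell counts (row-wise: group1 = a/b, group2 = c/d).
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stop("counts must be non-negative")
  n <- sum(cnt)
  if (any(c(a + b, c + d, a + c, b + d) == 0))
    stop("all table margins must be positive")
  chi2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
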