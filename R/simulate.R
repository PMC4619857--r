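#' Specify a synthetic two-group thickness study
#'
#' Bundles the generative parameters for a case-control cortical-thickness
#' cohort: demographics per group (age, sex, PSQI sleep-quality score),
#' per-vertex covariate effects, a latent seed factor whose coupling to the
#' cortex may differ between groups, and spatially smooth measurement
#' noise. The demographic defaults emulate a published primary-insomnia
#' cohort: n = 35 per group; patient (PI) PSQI ~ 12.57 (SD 3.93) truncated
#' to the 5-21 range; control (HC) PSQI ~ 2.26 (SD 1.36) truncated to 0-4
#' (controls are good sleepers by inclusion, every HC score < 5); ages
#' 39.3 +/- 8.6 vs 34.9 +/- 10.7 years; 5/30 vs 9/26 males/females.
#'
#' The thickness model for subject i at vertex v is
#' \deqn{T_i(v) = \mu(v) + a_{age}(v) age_i + a_{sex}(v) sex_i +
#'   [b_0(v) + \Delta b(v) g_i] L_i + \epsilon_i(v)}
#' with a latent per-subject seed factor \eqn{L_i ~ N(0, seed_signal_sd)}
#' added as-is to every seed-region vertex, group indicator \eqn{g_i}
#' (HC = 0, PI = 1), sex coded F = 0 / M = 1, and \eqn{\epsilon} white
#' Gaussian noise of sd `noise_sd` diffused to spatial FWHM `noise_fwhm`.
#' The latent-factor construction makes the true per-group covariance slope
#' (b0 for HC, b0 + delta for PI) an explicit, recoverable parameter.
#'
#' @param mesh [surface_mesh()] the fields live on.
#' @param n_per_group subjects per group (>= 3).
#' @param age_mean,age_sd length-2 vectors `c(hc=, pi=)`, years.
#' @param age_range truncation bounds for age, years.
#' @param male_prob probability of male sex per group `c(hc=, pi=)`.
#' @param psqi_mean,psqi_sd PSQI truncated-normal parameters `c(hc=, pi=)`.
#' @param psqi_range_hc,psqi_range_pi PSQI truncation intervals (the
#'   instrument range is 0-21; defaults encode the HC < 5 inclusion rule).
#' @param baseline_mean per-vertex mean thickness mu(v), mm (scalar
#'   recycled).
#' @param a_age,a_sex per-vertex covariate effects, mm per year / mm
#'   (scalar recycled).
#' @param seed_region [seed_region()] receiving the latent factor, or NULL
#'   for no seed signal.
#' @param seed_signal_sd sd of the latent seed factor L, mm.
#' @param coupling_hc per-vertex HC coupling slope b0(v), dimensionless.
#' @param coupling_delta per-vertex group difference in slope delta_b(v).
#' @param noise_sd sd of the white noise before smoothing, mm.
#' @param noise_fwhm spatial FWHM the noise is smoothed to, mm (0 = white).
#' @param rng_seed integer seed; everything downstream is deterministic
#'   given it.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(mesh,
                            n_per_group = 35,
                            age_mean = c(hc = 34.9, pi = 39.3),
                            age_sd = c(hc = 10.7, pi = 8.6),
                            age_range = c(18, 80),
                            male_prob = c(hc = 9 / 35, pi = 5 / 35),
                            psqi_mean = c(hc = 2.26, pi = 12.57),
                            psqi_sd = c(hc = 1.36, pi = 3.93),
                            psqi_range_hc = c(0, 4),
                            psqi_range_pi = c(5, 21),
                            baseline_mean = 2.5,
                            a_age = 0,
                            a_sex = 0,
                            seed_region = NULL,
                            seed_signal_sd = 0.3,
                            coupling_hc = 0,
                            coupling_delta = 0,
                            noise_sd = 0.1,
                            noise_fwhm = 0,
                            rng_seed = 1L) {
  stopifnot_scalar(n_per_group, "n_per_group", integer = TRUE)
  if (n_per_group < 3) stop("'n_per_group' must be >= 3")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (noise_fwhm < 0) stop("'noise_fwhm' must be >= 0")
  if (seed_signal_sd < 0) stop("'seed_signal_sd' must be >= 0")
  nv <- nrow(mesh$vertices)
  expand <- function(x, name) {
    if (length(x) == 1L) rep(as.numeric(x), nv)
    else if (length(x) == nv) as.numeric(x)
    else stop("'", name, "' must be scalar or one value per vertex")
  }
  spec <- list(mesh = mesh, n_per_group = as.integer(n_per_group),
               age_mean = age_mean, age_sd = age_sd, age_range = age_range,
               male_prob = male_prob,
               psqi_mean = psqi_mean, psqi_sd = psqi_sd,
               psqi_range_hc = psqi_range_hc, psqi_range_pi = psqi_range_pi,
               baseline_mean = expand(baseline_mean, "baseline_mean"),
               a_age = expand(a_age, "a_age"),
               a_sex = expand(a_sex, "a_sex"),
               seed_region = seed_region,
               seed_signal_sd = seed_signal_sd,
               coupling_hc = expand(coupling_hc, "coupling_hc"),
               coupling_delta = expand(coupling_delta, "coupling_delta"),
               noise_sd = noise_sd, noise_fwhm = noise_fwhm,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "simulation_spec"
  spec
}

#' Draw a synthetic cohort table
#'
#' Ages and PSQI scores come from truncated normals (inverse-CDF sampling,
#' PSQI rounded to integer scores), sex from per-group Bernoulli draws.
#' Deterministic given `spec$rng_seed`.
#'
#' @param spec a [simulation_spec()].
#' @return data.frame of class `cohort_table`: `subject_id`, `group`
#'   (HC = 0, PI = 1), `age` (years), `sex` (F = 0, M = 1), `psqi`
#'   (integer 0-21).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_per_group
  with_seed(spec$rng_seed, {
    age_hc <- rtruncnorm(n, spec$age_mean[["hc"]], spec$age_sd[["hc"]],
                         spec$age_range[1], spec$age_range[2])
    age_pi <- rtruncnorm(n, spec$age_mean[["pi"]], spec$age_sd[["pi"]],
                         spec$age_range[1], spec$age_range[2])
    sex_hc <- as.integer(stats::runif(n) < spec$male_prob[["hc"]])
    sex_pi <- as.integer(stats::runif(n) < spec$male_prob[["pi"]])
    # PSQI location is moment-matched so the truncated distribution keeps
    # the configured group mean despite the instrument-range truncation
    mu_hc <- match_truncnorm_mu(spec$psqi_mean[["hc"]], spec$psqi_sd[["hc"]],
                                spec$psqi_range_hc[1], spec$psqi_range_hc[2])
    mu_pi <- match_truncnorm_mu(spec$psqi_mean[["pi"]], spec$psqi_sd[["pi"]],
                                spec$psqi_range_pi[1], spec$psqi_range_pi[2])
    psqi_hc <- round(rtruncnorm(n, mu_hc, spec$psqi_sd[["hc"]],
                                spec$psqi_range_hc[1], spec$psqi_range_hc[2]))
    psqi_pi <- round(rtruncnorm(n, mu_pi, spec$psqi_sd[["pi"]],
                                spec$psqi_range_pi[1], spec$psqi_range_pi[2]))
    df <- data.frame(
      subject_id = sprintf("%s%03d", rep(c("HC", "PI"), each = n),
                           c(seq_len(n), seq_len(n))),
      group = rep(c(0L, 1L), each = n),
      age = c(age_hc, age_pi),
      sex = c(sex_hc, sex_pi),
      psqi = as.integer(c(psqi_hc, psqi_pi)))
    class(df) <- c("cohort_table", "data.frame")
    df
  })
}

# Sparse one-step diffusion operator S = (1 - lambda) I + lambda * D^-1 A,
# acting on per-vertex fields; rows sum to one, so constants are fixed
# points.
smoothing_operator <- function(mesh, lambda) {
  nv <- nrow(mesh$vertices)
  e <- mesh$edges
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = nv)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nv, nv))
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  Matrix::Diagonal(nv, 1 - lambda) + lambda * W
}

# Number of full diffusion steps (and the fractional last-step lambda)
# that give a lazy-random-walk kernel of per-axis variance fwhm^2/(8 ln 2).
# One step at mixing weight lambda adds lambda * mean(edge^2) / 2 variance
# per tangent axis.
smoothing_steps <- function(mesh, fwhm, lambda = 0.5) {
  el2 <- mean(mesh_metrics(mesh)$edge_lengths^2)
  sigma2 <- fwhm^2 / (8 * log(2))
  k <- 2 * sigma2 / (lambda * el2)
  list(full = floor(k), frac_lambda = (k - floor(k)) * lambda, k = k)
}

#' Smooth per-vertex fields by calibrated neighbor-averaging diffusion
#'
#' Iterated lazy-random-walk averaging over the mesh edge graph, with the
#' iteration count calibrated so that an initially white field attains an
#' approximately Gaussian spatial autocorrelation of the requested FWHM
#' (central-limit behavior of the walk kernel). `fwhm = 0` is the identity
#' and constant fields are exact fixed points. Note that diffusion shrinks
#' the marginal variance of a white field; `noise_sd` in
#' [simulation_spec()] is therefore the pre-smoothing sd.
#'
#' @param mesh a [surface_mesh()].
#' @param values per-vertex numeric vector, or a matrix with one column per
#'   vertex (rows smoothed independently).
#' @param fwhm target FWHM in mm (>= 0).
#' @param lambda mixing weight per step in (0, 1]; smaller values make the
#'   kernel more Gaussian at the cost of more iterations.
#' @return smoothed vector or matrix, same shape as `values`.
#' @export
smooth_field <- function(mesh, values, fwhm, lambda = 0.5) {
  stopifnot_scalar(fwhm, "fwhm")
  if (fwhm < 0) stop("'fwhm' must be >= 0")
  if (fwhm == 0) return(values)
  vec <- is.null(dim(values))
  Y <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  if (ncol(Y) != nrow(mesh$vertices))
    stop("'values' must have one entry per mesh vertex")
  st <- smoothing_steps(mesh, fwhm, lambda)
  S <- smoothing_operator(mesh, lambda)
  St <- Matrix::t(S)
  for (i in seq_len(st$full)) Y <- as.matrix(Y %*% St)
  if (st$frac_lambda > 1e-12) {
    Sf <- Matrix::t(smoothing_operator(mesh, st$frac_lambda))
    Y <- as.matrix(Y %*% Sf)
  }
  if (vec) drop(Y) else Y
}

#' Generate a synthetic subjects-by-vertices thickness dataset
#'
#' Realizes the generative model documented in [simulation_spec()]:
#' baseline + covariate effects + seed-driven coupling + smooth noise.
#' Deterministic given `spec$rng_seed` (a substream independent of the
#' cohort draw).
#'
#' @param mesh a [surface_mesh()]; must match `spec$mesh` dimensions.
#' @param cohort a cohort table from [sample_cohort()] (or equivalent
#'   columns `group`, `age`, `sex`).
#' @param spec a [simulation_spec()].
#' @return object of class `thickness_dataset`: list with `thickness`
#'   (n x V matrix, mm), `mesh`, `cohort`, `latent_seed` (the true per-
#'   subject factor, for simulation studies), and `spec`.
#' @export
generate_thickness <- function(mesh, cohort, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  nv <- nrow(mesh$vertices)
  if (length(spec$baseline_mean) != nv)
    stop("spec was built for a mesh with ", length(spec$baseline_mean),
         " vertices, not ", nv)
  n <- nrow(cohort)
  if (!all(c("group", "age", "sex") %in% names(cohort)))
    stop("cohort must have columns group, age, sex")
  with_seed(spec$rng_seed + 1L, {
    L <- stats::rnorm(n, 0, spec$seed_signal_sd)
    E <- matrix(stats::rnorm(n * nv, 0, spec$noise_sd), n, nv)
  })
  if (spec$noise_fwhm > 0 && spec$noise_sd > 0)
    E <- smooth_field(mesh, E, spec$noise_fwhm)
  Tm <- matrix(spec$baseline_mean, n, nv, byrow = TRUE) +
    cohort$age %o% spec$a_age +
    cohort$sex %o% spec$a_sex +
    L %o% spec$coupling_hc +
    (L * cohort$group) %o% spec$coupling_delta +
    E
  if (!is.null(spec$seed_region))
    Tm[, spec$seed_region$vertex_indices] <-
      Tm[, spec$seed_region$vertex_indices] + L
  colnames(Tm) <- sprintf("v%05d", seq_len(nv) - 1L)
  structure(list(thickness = Tm, mesh = mesh, cohort = cohort,
                 latent_seed = L, spec = spec),
            class = "thickness_dataset")
}

#' @export
print.thickness_dataset <- function(x, ...) {
  cat("thickness_dataset: ", nrow(x$thickness), " subjects x ",
      ncol(x$thickness), " vertices\n", sep = "")
  cat("  groups: ", sum(x$cohort$group == 0), " HC / ",
      sum(x$cohort$group == 1), " PI\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `cohort.tsv` (`subject_id group age sex psqi`), `thickness.tsv`
#' (one row per subject, 0-based-named vertex columns), and a JSON sidecar
#' `simulation.json` recording the scalar simulation parameters and RNG
#' seed. Output is bitwise-deterministic for a fixed spec.
#'
#' @param dataset a `thickness_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             thickness = file.path(dir, "thickness.tsv"),
             spec = file.path(dir, "simulation.json"))
  write_tsv(dataset$cohort, paths["cohort"])
  th <- as.data.frame(signif(dataset$thickness, 10))
  th <- cbind(subject_id = dataset$cohort$subject_id, th)
  write_tsv(th, paths["thickness"])
  sp <- dataset$spec
  scalars <- sp[!vapply(sp, function(x)
    inherits(x, "surface_mesh") || length(x) > 2L, logical(1))]
  scalars$seed_region <- if (is.null(sp$seed_region)) NULL else
    list(name = sp$seed_region$name,
         vertex_index_0based = sp$seed_region$vertex_indices - 1L)
  jsonlite::write_json(scalars, paths["spec"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a thickness matrix written by [write_dataset()]
#'
#' @param path `thickness.tsv` path.
#' @return numeric matrix, subjects x vertices, rownames = subject ids.
#' @export
read_thickness <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
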