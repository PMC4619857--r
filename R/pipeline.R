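#' Configure a full structural-covariance run
#'
#' Inputs come either from files (`mesh_path`, `thickness_path`,
#' `cohort_path`, `labels_path`) or from a [simulation_spec()] plus a list
#' of seed regions. The analyses toggle the four stages: vertex-wise
#' thickness comparison and PSQI correlation, per-group seed covariance
#' maps, group-interaction maps, and PSQI-modulation maps.
#'
#' @param mesh_path,thickness_path,cohort_path,labels_path input files
#'   (all four required unless `sim_spec` is given).
#' @param sim_spec a [simulation_spec()]; when given, the cohort and
#'   thickness data are simulated instead of loaded.
#' @param seeds list of [seed_region()] objects, or NULL to use all labels
#'   from `labels_path` (or the spec's seed region).
#' @param analyses character subset of
#'   `c("thickness", "scn_per_group", "group_interaction",
#'   "psqi_modulation")`.
#' @param cluster_forming_p uncorrected cluster-forming threshold.
#' @param fwe_alpha familywise alpha for flagging significant clusters.
#' @param trend_p uncorrected trend threshold.
#' @param rng_seed integer seed governing any simulation.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(mesh_path = NULL, thickness_path = NULL,
                       cohort_path = NULL, labels_path = NULL,
                       sim_spec = NULL, seeds = NULL,
                       analyses = c("thickness", "scn_per_group",
                                    "group_interaction", "psqi_modulation"),
                       cluster_forming_p = 0.001, fwe_alpha = 0.05,
                       trend_p = 0.05, rng_seed = 1L, out_dir = "scn_out") {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (!length(analyses)) stop("select at least one analysis")
  for (p in c(cluster_forming_p, fwe_alpha, trend_p))
    if (p <= 0 || p >= 1) stop("thresholds must lie in (0, 1)")
  if (is.null(sim_spec) &&
      (is.null(mesh_path) || is.null(thickness_path) || is.null(cohort_path)))
    stop("either a simulation spec or mesh/thickness/cohort paths are required")
  structure(list(mesh_path = mesh_path, thickness_path = thickness_path,
                 cohort_path = cohort_path, labels_path = labels_path,
                 sim_spec = sim_spec, seeds = seeds, analyses = analyses,
                 cluster_forming_p = cluster_forming_p,
                 fwe_alpha = fwe_alpha, trend_p = trend_p,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "run_config")
}

#' Demographics table with group tests
#'
#' Per-group n, sex split, mean/SD of age and PSQI; chi-square p for the
#' sex split, two-tailed pooled t for age, one-tailed pooled t (PI > HC)
#' for PSQI — the conventions of a case-control demographics table.
#'
#' @param cohort cohort data.frame with `group`, `age`, `sex`, `psqi`.
#' @return data.frame, one row per variable, columns `variable`, `pi`,
#'   `hc`, `p`, `test`.
#' @export
demographics_report <- function(cohort) {
  g <- cohort$group
  if (length(unique(g)) < 2) stop("cohort must contain both groups")
  hc <- cohort[g == 0, ]; pi_ <- cohort[g == 1, ]
  fmt <- function(x) sprintf("%.2f, %.2f", mean(x), stats::sd(x))
  sex_p <- chi_square_2x2(sum(pi_$sex == 1), sum(pi_$sex == 0),
                          sum(hc$sex == 1), sum(hc$sex == 0))$p
  age_p <- two_sample_t(mean(pi_$age), stats::sd(pi_$age), nrow(pi_),
                        mean(hc$age), stats::sd(hc$age), nrow(hc),
                        tails = 2)$p
  psqi_p <- two_sample_t(mean(pi_$psqi), stats::sd(pi_$psqi), nrow(pi_),
                         mean(hc$psqi), stats::sd(hc$psqi), nrow(hc),
                         tails = 1)$p
  data.frame(
    variable = c("n", "gender_male_female", "age_years", "psqi_total"),
    pi = c(nrow(pi_), sprintf("%d/%d", sum(pi_$sex == 1), sum(pi_$sex == 0)),
           fmt(pi_$age), fmt(pi_$psqi)),
    hc = c(nrow(hc), sprintf("%d/%d", sum(hc$sex == 1), sum(hc$sex == 0)),
           fmt(hc$age), fmt(hc$psqi)),
    p = c(NA, sex_p, age_p, psqi_p),
    test = c(NA, "chi_square", "two_tailed_t", "one_tailed_t"),
    stringsAsFactors = FALSE)
}

# RFT-correct one statmap for both tails and write map/cluster/mask files.
# File names in the returned record are relative to the output directory,
# so reruns into different directories produce identical reports.
correct_and_write <- function(statmap, mesh, config, stem, out) {
  sm_file <- paste0(stem, "_statmap.tsv")
  write_statmap(statmap, file.path(out, sm_file))
  smooth <- estimate_smoothness(residuals(statmap), mesh,
                                exclude = statmap$flagged,
                                n_effective = statmap$df)
  files <- list(statmap = sm_file)
  for (tail in c("positive", "negative")) {
    lab <- if (tail == "positive") "increased" else "decreased"
    tab <- cluster_fwe(statmap, smooth, mesh,
                       cluster_forming_p = config$cluster_forming_p,
                       tail = tail)
    cl_file <- paste0(stem, "_", lab, "_clusters.tsv")
    write_cluster_table(tab, file.path(out, cl_file))
    mask <- uncorrected_mask(statmap, config$trend_p, tail)
    mk_file <- paste0(stem, "_", lab, "_trend_mask.tsv")
    write_tsv(data.frame(vertex_index = which(mask) - 1L),
              file.path(out, mk_file))
    files[[paste0(lab, "_clusters")]] <- cl_file
    files[[paste0(lab, "_trend_mask")]] <- mk_file
    files[[paste0(lab, "_n_significant")]] <-
      sum(tab$p_fwe < config$fwe_alpha)
  }
  files$fwhm <- smooth$fwhm
  files
}

#' Run the full seed-based covariance analysis
#'
#' Executes, in order: input loading or simulation; demographics tests;
#' vertex-wise thickness group comparison and thickness-PSQI correlation;
#' covariate residualization and, per seed, per-group covariance maps,
#' seed-by-group interaction maps and seed-by-PSQI modulation maps; then
#' random-field correction (both tails, labelled increased/decreased) and
#' uncorrected trend masks for every map. All outputs are plain text under
#' `config$out_dir`; the run is deterministic given `config$rng_seed`, and
#' a failed stage removes its partial outputs.
#'
#' Seed vertices stay in the output maps (covariance of a seed with itself
#' is trivially high); they are listed in the per-seed JSON metadata
#' rather than silently masked.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: nested list of output files and
#'   summary numbers per analysis/seed/tail, plus the demographics table
#'   and provenance (config hash, package version, rng seed).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  tryCatch({
    stage <- "load_inputs"
    if (!is.null(config$sim_spec)) {
      spec <- config$sim_spec
      spec$rng_seed <- config$rng_seed
      mesh <- spec$mesh
      cohort <- sample_cohort(spec)
      ds <- generate_thickness(mesh, cohort, spec)
      Y <- ds$thickness
      seeds <- config$seeds
      if (is.null(seeds) && !is.null(spec$seed_region))
        seeds <- list(spec$seed_region)
    } else {
      mesh <- read_surface(config$mesh_path)
      cohort <- read_tsv(config$cohort_path)
      Y <- read_thickness(config$thickness_path)
      seeds <- config$seeds
      if (is.null(seeds)) {
        if (is.null(config$labels_path))
          stop("no seed regions: give 'seeds' or 'labels_path'")
        seeds <- read_labels(config$labels_path, mesh)
      }
      if (nrow(Y) != nrow(cohort))
        stop("thickness rows (", nrow(Y), ") != cohort rows (",
             nrow(cohort), ")")
      if (ncol(Y) != nrow(mesh$vertices))
        stop("thickness columns != mesh vertex count")
    }
    if (is.null(seeds) || !length(seeds))
      stop("no seed regions available")
    names(seeds) <- vapply(seeds, function(s) s$name, character(1))

    report <- list(demographics = NULL, analyses = list(),
                   provenance = list(
                     package_version =
                       as.character(utils::packageVersion("scnsurf")),
                     rng_seed = config$rng_seed,
                     cluster_forming_p = config$cluster_forming_p,
                     fwe_alpha = config$fwe_alpha,
                     trend_p = config$trend_p,
                     config_hash = config_hash(config)))

    stage <- "demographics"
    demo <- demographics_report(cohort)
    write_tsv(demo, file.path(out, "demographics.tsv"))
    report$demographics <- demo

    stage <- "thickness_maps"
    if ("thickness" %in% config$analyses) {
      report$analyses$thickness_group <- correct_and_write(
        thickness_group_map(Y, cohort), mesh, config, "thickness_group", out)
      report$analyses$thickness_psqi <- correct_and_write(
        thickness_psqi_map(Y, cohort), mesh, config, "thickness_psqi", out)
    }

    stage <- "residualize"
    Yadj <- residualize_covariates(Y, cohort)

    for (s in seeds) {
      sv <- seed_mean(Yadj, s)
      jsonlite::write_json(
        list(seed = s$name,
             vertex_index_0based = s$vertex_indices - 1L),
        file.path(out, paste0("seed_", s$name, ".json")), auto_unbox = TRUE)
      if ("scn_per_group" %in% config$analyses) {
        stage <- paste0("scn_per_group:", s$name)
        for (grp in c(0L, 1L)) {
          gl <- if (grp == 0L) "HC" else "PI"
          rows <- cohort$group == grp
          report$analyses[[paste0("scn_", s$name, "_", gl)]] <-
            correct_and_write(scn_map(Yadj[rows, , drop = FALSE], sv[rows]),
                              mesh, config, paste0("scn_", s$name, "_", gl),
                              out)
        }
      }
      if ("group_interaction" %in% config$analyses) {
        stage <- paste0("group_interaction:", s$name)
        report$analyses[[paste0("interaction_", s$name)]] <-
          correct_and_write(interaction_map(Yadj, sv, cohort$group, "group"),
                            mesh, config, paste0("interaction_", s$name), out)
      }
      if ("psqi_modulation" %in% config$analyses) {
        stage <- paste0("psqi_modulation:", s$name)
        report$analyses[[paste0("modulation_", s$name)]] <-
          correct_and_write(interaction_map(Yadj, sv, cohort$psqi, "psqi"),
                            mesh, config, paste0("modulation_", s$name), out)
      }
    }

    stage <- "report"
    jsonlite::write_json(report_json(report),
                         file.path(out, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    class(report) <- "run_report"
    report
  }, error = function(e) {
    if (created) unlink(out, recursive = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

config_hash <- function(config) {
  # hash of the analysis parameters (paths excluded so the same analysis
  # run into two directories hashes identically); provenance only
  flat <- config[c("analyses", "cluster_forming_p", "fwe_alpha", "trend_p",
                   "rng_seed")]
  txt <- as.character(jsonlite::toJSON(flat, auto_unbox = TRUE))
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

report_json <- function(report) {
  list(demographics = report$demographics,
       analyses = report$analyses,
       provenance = report$provenance)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Structural covariance run report\n")
  cat("  demographics: PSQI p = ",
      format(x$demographics$p[4], digits = 3),
      ", age p = ", format(x$demographics$p[3], digits = 3),
      ", sex p = ", format(x$demographics$p[2], digits = 3), "\n", sep = "")
  for (nm in names(x$analyses)) {
    a <- x$analyses[[nm]]
    cat("  ", nm, ": FWHM ", format(a$fwhm, digits = 4), " mm; ",
        a$increased_n_significant, " increased / ",
        a$decreased_n_significant,
        " decreased FWE-significant cluster(s)\n", sep = "")
  }
  invisible(x)
}
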