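#' Estimate residual-field smoothness and resel counts
#'
#' Standard residual-based estimator for random-field correction on a
#' triangulated surface. Per-vertex residual vectors are normalized to unit
#' length; for every mesh edge the mean-squared difference of normalized
#' residuals \eqn{\Delta^2_e = \sum_j (u_{1j} - u_{2j})^2} measures local
#' roughness, and under a Gaussian autocorrelation model converts to a
#' local smoothness \eqn{FWHM_e = \ell_e \sqrt{4 \ln 2 / \Delta^2_e}}.
#' Resel (resolution-element) counts follow from the mesh measured in FWHM
#' units: each edge has resel length \eqn{\ell_e / FWHM_e}, triangles get
#' resel areas by Heron's formula on their resel edge lengths, and
#'
#' * `resels[1]` (dimension 0) is the Euler characteristic of the search
#'   region,
#' * `resels[2]` (dimension 1) is half the boundary length in FWHM units
#'   (zero for a closed surface),
#' * `resels[3]` (dimension 2) is the summed triangle resel area.
#'
#' The global FWHM is the area-weighted aggregate
#' `sqrt(total_area / resels_2)`, so `resels_2 = area / FWHM^2` by
#' construction. A per-edge local FWHM field is kept for diagnostics but
#' the global value drives the p-values.
#'
#' @param residuals subjects x vertices residual matrix (e.g.
#'   `residuals(statmap)`).
#' @param mesh the [surface_mesh()] the residuals live on.
#' @param exclude optional logical per-vertex vector of degenerate
#'   (zero-residual) vertices to leave out, e.g. `statmap$flagged`.
#' @param n_effective residual degrees of freedom to record.
#' @return object of class `smoothness_estimate`: `fwhm` (mm, global),
#'   `fwhm_edge` (per edge), `resels` (length-3, dimensions 0..2),
#'   `total_area`, `n_effective`.
#' @export
estimate_smoothness <- function(residuals, mesh, exclude = NULL,
                                n_effective = NULL) {
  R <- as.matrix(residuals)
  nv <- nrow(mesh$vertices)
  if (ncol(R) != nv) stop("residuals must have one column per vertex")
  if (nrow(R) < 2) stop("need residual df >= 2")
  norms <- sqrt(colSums(R^2))
  ok <- norms > 0
  if (!is.null(exclude)) ok <- ok & !exclude
  if (!any(ok)) stop("all vertices are degenerate; cannot estimate smoothness")
  U <- R
  U[, ok] <- sweep(R[, ok, drop = FALSE], 2, norms[ok], "/")
  e <- mesh$edges
  keep <- ok[e[, 1]] & ok[e[, 2]]
  if (!any(keep)) stop("no usable edges for smoothness estimation")
  delta2 <- colSums((U[, e[, 1], drop = FALSE] -
                     U[, e[, 2], drop = FALSE])^2)
  delta2[!keep] <- NA
  if (all(delta2[keep] < 1e-12))
    stop("zero residual roughness (constant field); smoothness undefined")
  lens <- mesh_metrics(mesh)$edge_lengths
  fwhm_edge <- lens * sqrt(4 * log(2) / delta2)
  # mesh measured in FWHM units: resel edge length = l / FWHM_edge
  rlen <- sqrt(delta2 / (4 * log(2)))
  rlen[!keep] <- mean(rlen[keep])          # neutral fill for excluded edges
  edge_id <- function(i, j) match(paste(pmin(i, j), pmax(i, j)),
                                  paste(e[, 1], e[, 2]))
  tr <- mesh$triangles
  ra <- rlen[edge_id(tr[, 1], tr[, 2])]
  rb <- rlen[edge_id(tr[, 2], tr[, 3])]
  rc <- rlen[edge_id(tr[, 3], tr[, 1])]
  s <- (ra + rb + rc) / 2
  heron <- s * (s - ra) * (s - rb) * (s - rc)
  tri_resel <- sqrt(pmax(heron, 0))
  resels2 <- sum(tri_resel)
  area <- sum(mesh$triangle_areas)
  fwhm <- sqrt(area / resels2)
  # boundary edges (in exactly one triangle) contribute the 1-D resel count
  cnt <- edge_triangle_counts(mesh$triangles, e)
  resels1 <- sum(rlen[cnt == 1L]) / 2
  resels0 <- euler_characteristic(mesh)
  structure(list(fwhm = fwhm, fwhm_edge = fwhm_edge,
                 resels = c(resels0, resels1, resels2),
                 total_area = area,
                 n_effective = if (is.null(n_effective)) nrow(R) else
                   n_effective),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat("smoothness_estimate: FWHM ", format(x$fwhm, digits = 4),
      " mm; resels (dim 0..2): ",
      paste(format(x$resels, digits = 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Euler-characteristic densities of a t random field
#'
#' Closed-form EC densities for Student-t fields on a 2-D search region,
#' per dimension d = 0, 1, 2 (surface analysis only):
#' \deqn{\rho_0 = P(T_\nu \ge t)}
#' \deqn{\rho_1 = \frac{\sqrt{4\ln 2}}{2\pi} (1 + t^2/\nu)^{-(\nu-1)/2}}
#' \deqn{\rho_2 = \frac{4\ln 2}{(2\pi)^{3/2}}
#'   \frac{\Gamma((\nu+1)/2)}{\sqrt{\nu/2}\,\Gamma(\nu/2)}
#'   \, t \, (1 + t^2/\nu)^{-(\nu-1)/2}}
#' in units of resels^-d. As df grows they converge to the Gaussian-field
#' densities.
#'
#' @param t threshold(s).
#' @param df degrees of freedom (>= 1).
#' @param dimension 0, 1 or 2.
#' @return density value(s), vectorized over `t`.
#' @export
ec_density_t <- function(t, df, dimension) {
  if (df < 1) stop("'df' must be >= 1")
  if (!dimension %in% 0:2)
    stop("'dimension' must be 0, 1 or 2 (surface analysis only)")
  if (dimension == 0) return(stats::pt(t, df, lower.tail = FALSE))
  body <- (1 + t^2 / df)^(-(df - 1) / 2)
  if (dimension == 1) return(sqrt(4 * log(2)) / (2 * pi) * body)
  # dimension 2; the df-dependent constant -> 1 as df -> Inf
  lc <- lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df / 2)
  (4 * log(2)) / (2 * pi)^1.5 * exp(lc) * t * body
}

# Expected Euler characteristic of the excursion set above t:
# sum_d resels_d * rho_d(t). The standard FWE bound for the field maximum.
expected_ec <- function(t, df, resels) {
  resels[1] * ec_density_t(t, df, 0) +
    resels[2] * ec_density_t(t, df, 1) +
    resels[3] * ec_density_t(t, df, 2)
}

#' Peak familywise-error corrected p-values
#'
#' Corrected p for each vertex's t value via the expected-Euler-
#' characteristic bound \eqn{p(t) = \min(1, \sum_d R_d \rho_d(t))},
#' monotone non-increasing in t. Degenerate vertices flagged with infinite
#' t get p = 0 in their tail.
#'
#' @param statmap a `statmap`.
#' @param smoothness a [estimate_smoothness()] result.
#' @param tail "positive" (tests large t) or "negative" (large -t).
#' @return per-vertex corrected p values in (0, 1].
#' @export
peak_fwe <- function(statmap, smoothness, tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  if (!inherits(smoothness, "smoothness_estimate"))
    stop("'smoothness' must come from estimate_smoothness()")
  tv <- if (tail == "positive") statmap$t else -statmap$t
  # the EC approximation is an excursion bound, valid for thresholds >= 0;
  # below 0 the corrected p saturates at 1
  p <- pmin(1, expected_ec(pmax(tv, 0), statmap$df, smoothness$resels))
  p[tv == Inf] <- 0
  pmax(p, 0)
}

#' Cluster-extent familywise-error correction
#'
#' Thresholds the (tail-selected) t field at the value whose uncorrected p
#' equals `cluster_forming_p`, extracts maximal connected components under
#' mesh-edge adjacency, and assigns each cluster a corrected p from the
#' standard expected-cluster framework for 2-D fields: with
#' m = E[number of clusters] (the expected EC at the forming threshold) and
#' E[S] = resels_2 * rho_0(t_c) / m the expected cluster extent in resels,
#' the extent null distribution is exponential,
#' P(S >= s) = exp(-s / E[S]), and
#' p_fwe = 1 - exp(-m * P(S >= s)). Every component is reported, including
#' those with p_fwe > 0.05; the forming threshold, tail, df and FWHM ride
#' along as attributes.
#'
#' @param statmap a `statmap`.
#' @param smoothness a [estimate_smoothness()] result.
#' @param mesh the [surface_mesh()].
#' @param cluster_forming_p uncorrected cluster-forming p in (0, 1);
#'   default 0.001.
#' @param tail "positive" or "negative".
#' @return object of class `cluster_table`: data.frame with `cluster_id`,
#'   `n_vertices`, `resels`, `peak_t`, `peak_vertex` (1-based), `p_fwe`,
#'   sorted by `p_fwe`; member vertex indices in `attr(, "members")`, run
#'   metadata in `attr(, "meta")`. Empty when nothing is suprathreshold.
#' @export
cluster_fwe <- function(statmap, smoothness, mesh,
                        cluster_forming_p = 0.001,
                        tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  if (cluster_forming_p <= 0 || cluster_forming_p >= 1)
    stop("'cluster_forming_p' must be in (0, 1)")
  tv <- if (tail == "positive") statmap$t else -statmap$t
  tc <- stats::qt(cluster_forming_p, statmap$df, lower.tail = FALSE)
  supra <- which(tv > tc)   # flagged +Inf vertices are suprathreshold
  meta <- list(tail = tail, cluster_forming_p = cluster_forming_p,
               t_threshold = tc, df = statmap$df, fwhm = smoothness$fwhm,
               resels = smoothness$resels, contrast = statmap$contrast)
  empty <- data.frame(cluster_id = integer(0), n_vertices = integer(0),
                      resels = numeric(0), peak_t = numeric(0),
                      peak_vertex = integer(0), p_fwe = numeric(0))
  if (!length(supra))
    return(structure(empty, members = list(), meta = meta,
                     class = c("cluster_table", "data.frame")))
  comp <- connected_components(mesh, supra)
  # per-vertex area: one third of incident triangle area
  va <- vertex_areas(mesh)
  m_clusters <- max(expected_ec(tc, statmap$df, smoothness$resels), 1e-12)
  exp_resels <- smoothness$resels[3] *
    ec_density_t(tc, statmap$df, 0) / m_clusters
  rows <- lapply(seq_along(comp), function(k) {
    vs <- comp[[k]]
    ext <- sum(va[vs]) / smoothness$fwhm^2
    pk <- vs[which.max(tv[vs])]
    p_ext <- exp(-ext / exp_resels)
    data.frame(cluster_id = k, n_vertices = length(vs), resels = ext,
               peak_t = statmap$t[pk], peak_vertex = pk,
               p_fwe = max(1 - exp(-m_clusters * p_ext), 1e-300))
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$p_fwe, -tab$resels)
  tab <- tab[ord, , drop = FALSE]
  tab$cluster_id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, members = comp[ord], meta = meta,
            class = c("cluster_table", "data.frame"))
}

# Maximal connected components of a vertex subset under mesh-edge
# adjacency; list of integer vectors of (1-based) vertex indices.
connected_components <- function(mesh, vertices) {
  e <- mesh$edges
  keep <- e[, 1] %in% vertices & e[, 2] %in% vertices
  g <- igraph::graph_from_edgelist(cbind(match(e[keep, 1], vertices),
                                         match(e[keep, 2], vertices)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(vertices) - igraph::vcount(g)))
  cc <- igraph::components(g)
  unname(lapply(split(seq_along(vertices), cc$membership),
                function(ix) sort(vertices[ix])))
}

vertex_areas <- function(mesh) {
  nv <- nrow(mesh$vertices)
  va <- numeric(nv)
  third <- rep(mesh$triangle_areas / 3, 3L)
  idx <- c(mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3])
  va_acc <- tapply(third, idx, sum)
  va[as.integer(names(va_acc))] <- va_acc
  va
}

#' @export
print.cluster_table <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("cluster_table (", meta$tail, " tail, forming p = ",
      meta$cluster_forming_p, ", t > ", format(meta$t_threshold, digits = 4),
      ", df = ", meta$df, ", FWHM = ", format(meta$fwhm, digits = 4),
      " mm)\n", sep = "")
  if (!nrow(x)) cat("  no suprathreshold clusters\n")
  else print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a cluster table to TSV plus JSON metadata
#'
#' Columns `cluster_id n_vertices resels peak_t peak_vertex p_fwe`
#' (peak_vertex 0-based on disk); the JSON sidecar carries FWHM, resels,
#' thresholds, tail and df.
#'
#' @param tab a `cluster_table`.
#' @param path output TSV path.
#' @export
write_cluster_table <- function(tab, path) {
  out <- as.data.frame(tab)
  if (nrow(out)) out$peak_vertex <- out$peak_vertex - 1L
  write_tsv(out, path)
  jsonlite::write_json(attr(tab, "meta"), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Uncorrected trend mask
#'
#' Vertices whose tail-appropriate uncorrected p falls below the
#' threshold; used for the p < 0.05 uncorrected trend maps that accompany
#' corrected results.
#'
#' @param statmap a `statmap`.
#' @param p uncorrected threshold in (0, 1).
#' @param tail "positive" or "negative".
#' @return logical per-vertex mask.
#' @export
uncorrected_mask <- function(statmap, p = 0.05,
                             tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  if (p <= 0 || p > 1) stop("'p' must be in (0, 1]")
  tv <- if (tail == "positive") statmap$t else -statmap$t
  tv > stats::qt(1 - p, statmap$df)
}
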