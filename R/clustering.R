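# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers with
# probability proportional to squared distance from the nearest chosen center
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Feature matrix for conformational clustering
#'
#' Superposes every frame onto a reference over the histone-core heavy
#' atoms, then flattens the coordinates of the chosen selection into one row
#' per frame. Selections follow the clustering scheme of the analysis:
#'
#' * `"dna"`: DNA backbone heavy atoms of the inner gyre plus the outer gyre
#'   of the annotation's opening arm (the non-opening outer gyre is
#'   excluded),
#' * `"h3"`: backbone heavy atoms of the whole H3 chains,
#' * `"h2ac"`: backbone heavy atoms of the H2A chains excluding the
#'   N-terminal tail residues.
#'
#' @param traj a `nuc_trajectory`
#' @param annotation a `nuc_annotation`
#' @param selection_tag `"dna"`, `"h3"` or `"h2ac"`
#' @param reference reference coordinates (default: topology model 1)
#' @param stride frame stride
#' @return numeric matrix `n_sampled_frames x (3 * n_selected_atoms)`; the
#'   sampled frame numbers are in `attr(, "frames")`, the selection in
#'   `attr(, "selection")`
#' @export
build_feature_matrix <- function(traj, annotation,
                                 selection_tag = c("dna", "h3", "h2ac"),
                                 reference = NULL, stride = 1L) {
  selection_tag <- match.arg(selection_tag)
  st <- traj$topology
  at <- st$atoms
  sel <- switch(selection_tag,
    dna = {
      opening_outer <- if (annotation$opening_arm == "3p")
        annotation$outer_3p else annotation$outer_5p
      sel_bp(st, annotation, c(annotation$inner, opening_outer),
             heavy = TRUE, backbone = TRUE)
    },
    h3 = {
      chains <- annotation$chain_map$chain[annotation$chain_map$histone == "H3"]
      idx <- which(at$chain %in% chains & at$name %in% .protein_backbone)
      sel_heavy(st, idx)
    },
    h2ac = {
      chains <- annotation$chain_map$chain[annotation$chain_map$histone == "H2A"]
      idx <- which(at$chain %in% chains & at$name %in% .protein_backbone)
      tl <- annotation$tails
      if (!is.null(tl)) {
        ntail <- tl[tl$histone == "H2A" & tl$terminus == "N", , drop = FALSE]
        for (i in seq_len(nrow(ntail)))
          idx <- idx[!(at$chain[idx] == ntail$chain[i] &
                       at$resid[idx] >= ntail$from[i] &
                       at$resid[idx] <= ntail$to[i])]
      }
      sel_heavy(st, idx)
    })
  if (length(sel) == 0L)
    stop("empty selection for tag '", selection_tag, "'")
  if (is.null(reference)) reference <- model_xyz(st)
  fit_sel <- sel_histone_core(st, annotation)
  frames <- seq(1L, n_frames(traj), by = stride)
  out <- matrix(NA_real_, length(frames), 3L * length(sel))
  for (i in seq_along(frames)) {
    fitted <- superpose(frame_xyz(traj, frames[i]), reference, fit_sel)$xyz
    out[i, ] <- as.numeric(t(fitted[sel, , drop = FALSE]))
  }
  attr(out, "frames") <- frames
  attr(out, "selection") <- sel
  out
}

#' k-means clustering of conformations
#'
#' Lloyd k-means with k-means++ seeding, run `n_init` times under a fixed
#' seed; the run with the lowest total within-cluster sum of squares is
#' kept. Cluster labels are then ranked by size (1 = largest; ties keep the
#' lower original label).
#'
#' @param x feature matrix (frames in rows), e.g. from
#'   [build_feature_matrix()]
#' @param k number of clusters (default 8)
#' @param seed RNG seed; identical `x`, `k` and `seed` give identical results
#' @param n_init number of k-means++ restarts
#' @param max_iter Lloyd iteration cap per restart
#' @param selection_tag optional tag recorded in the result
#' @return object of class `nuc_clusters`: `assignment` (per-row labels,
#'   size-ranked), `centroids`, `sizes`, `k`, `inertia`, `seed`,
#'   `selection_tag`, and `frames` (frame numbers, if `x` carries them)
#' @export
kmeans_cluster <- function(x, k = 8L, seed = 1L, n_init = 10L,
                           max_iter = 500L, selection_tag = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < k)
    stop("cannot form ", k, " clusters from ", nrow(x), " frames")
  best <- NULL
  .with_seed(seed, function() {
    for (run in seq_len(n_init)) {
      centers <- .kmeanspp_centers(x, k)
      km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                           iter.max = max_iter,
                                           algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss)
        best <<- km
    }
  })
  model <- structure(list(
    k = as.integer(k), assignment = best$cluster, centroids = best$centers,
    sizes = as.integer(best$size), inertia = best$tot.withinss,
    seed = as.integer(seed), selection_tag = selection_tag,
    frames = attr(x, "frames")), class = "nuc_clusters")
  rank_clusters(model)
}

#' @export
print.nuc_clusters <- function(x, ...) {
  cat(sprintf("<nuc_clusters> k = %d over %d frames%s; sizes: %s\n",
              x$k, length(x$assignment),
              if (is.null(x$selection_tag)) "" else
                paste0(" (", x$selection_tag, ")"),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Rank cluster labels by size
#'
#' Permutes cluster labels so that sizes are non-increasing (label 1 is the
#' largest cluster); ties keep the lower original label first.
#'
#' @param model a `nuc_clusters`
#' @return the model with relabeled assignment, centroids and sizes
#' @export
rank_clusters <- function(model) {
  ord <- order(-model$sizes, seq_along(model$sizes))
  relabel <- integer(model$k)
  relabel[ord] <- seq_len(model$k)
  model$assignment <- relabel[model$assignment]
  model$centroids <- model$centroids[ord, , drop = FALSE]
  rownames(model$centroids) <- seq_len(model$k)
  model$sizes <- model$sizes[ord]
  model
}

#' DNA-to-tail cluster co-occupancy matrix
#'
#' Entry (i, j) is the percentage of the frames of row cluster i (e.g. a DNA
#' conformation cluster) that fall in column cluster j (e.g. a histone-tail
#' configuration cluster). Every row sums to 100.
#'
#' @param row_model,col_model `nuc_clusters` objects (or plain assignment
#'   vectors) over the same frames
#' @return matrix of percentages, class `nuc_crosstab`
#' @export
cross_tabulate <- function(row_model, col_model) {
  a <- if (inherits(row_model, "nuc_clusters")) row_model$assignment
       else row_model
  b <- if (inherits(col_model, "nuc_clusters")) col_model$assignment
       else col_model
  if (length(a) != length(b))
    stop("cluster assignments cover different frame counts (",
         length(a), " vs ", length(b), ")")
  tab <- table(factor(a, levels = sort(unique(a))),
               factor(b, levels = sort(unique(b))))
  out <- 100 * sweep(unclass(tab), 1, rowSums(tab), `/`)
  dimnames(out) <- list(row = rownames(tab), col = colnames(tab))
  class(out) <- c("nuc_crosstab", class(out))
  out
}

#' @export
print.nuc_crosstab <- function(x, digits = 1, ...) {
  cat("<nuc_crosstab> row percentages (rows sum to 100):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Cluster positions in the opening-angle plane
#'
#' Per cluster: the mean (gamma1, gamma2) over member frames of one arm and
#' the cluster size, for plotting cluster centroids over the gamma
#' histogram. Clusters whose member frames have no defined angles yield
#' `NA` means.
#'
#' @param model a `nuc_clusters`
#' @param observables data.frame from [breathing_series()] covering the
#'   clustered frames
#' @param arm `"3p"` or `"5p"`
#' @return data.frame: cluster, size, mean_gamma1, mean_gamma2, mean_rg
#' @export
map_clusters_to_gamma <- function(model, observables, arm = c("3p", "5p")) {
  arm <- match.arg(arm)
  frames <- model$frames
  if (is.null(frames)) frames <- seq_along(model$assignment)
  idx <- match(frames, observables$frame)
  if (anyNA(idx))
    stop("observables do not cover all clustered frames")
  g1 <- observables[[paste0("gamma1_", arm)]][idx]
  g2 <- observables[[paste0("gamma2_", arm)]][idx]
  rg <- observables$rg[idx]
  out <- data.frame(cluster = seq_len(model$k), size = model$sizes,
                    mean_gamma1 = NA_real_, mean_gamma2 = NA_real_,
                    mean_rg = NA_real_)
  for (c in seq_len(model$k)) {
    in_c <- model$assignment == c
    if (any(in_c & is.finite(g1)))
      out$mean_gamma1[c] <- mean(g1[in_c], na.rm = TRUE)
    if (any(in_c & is.finite(g2)))
      out$mean_gamma2[c] <- mean(g2[in_c], na.rm = TRUE)
    if (any(in_c & is.finite(rg)))
      out$mean_rg[c] <- mean(rg[in_c], na.rm = TRUE)
  }
  out
}

#' 5th-95th percentile summary of a series
#'
#' Linear-interpolation percentiles (the default quantile type of
#' [stats::quantile()]) at the requested bounds, the format used for
#' two-sided range summaries of breathing observables.
#'
#' @param x non-empty numeric series (NAs dropped)
#' @param lo,hi percentile bounds (defaults 5 and 95)
#' @param label optional row label
#' @return data.frame: label, p_lo, p_hi
#' @export
percentile_summary <- function(x, lo = 5, hi = 95, label = "series") {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("empty series")
  q <- stats::quantile(x, probs = c(lo, hi) / 100, names = FALSE, type = 7)
  data.frame(label = label, p_lo = q[1], p_hi = q[2],
             stringsAsFactors = FALSE)
}
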