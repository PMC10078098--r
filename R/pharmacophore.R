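#' Perceive pharmacophoric features of a 3D pose
#'
#' Feature taxonomy (four classes):
#' \itemize{
#'   \item donor: position of an N or O bearing at least one hydrogen
#'   \item acceptor: position of an N or O that is not positively charged
#'   \item aromatic: centroid of each aromatic ring
#'   \item hydrophobic: centroid of each maximal connected group of three or
#'     more carbons that are neither aromatic nor bonded to a heteroatom
#' }
#' A hydroxyl oxygen is both donor and acceptor, by definition.
#'
#' @param pose `cvs_molecule` with 3D coordinates
#' @return data.frame: ftype, x, y, z
#' @export
perceive_features <- function(pose) {
  stopifnot(inherits(pose, "cvs_molecule"))
  if (is.null(pose$coords)) stopf("perceive_features: pose '%s' has no coordinates", pose$id)
  a <- pose$atoms
  xyz <- pose$coords
  feats <- list()
  add <- function(ftype, pt) feats[[length(feats) + 1]] <<-
    data.frame(ftype = ftype, x = pt[1], y = pt[2], z = pt[3], stringsAsFactors = FALSE)

  for (i in which(a$element %in% c("N", "O") & a$h >= 1)) add("donor", xyz[i, ])
  for (i in which(a$element %in% c("N", "O") & a$charge <= 0)) add("acceptor", xyz[i, ])

  for (ring in smallest_rings(pose)) {
    if (all(a$aromatic[ring])) add("aromatic", colMeans(xyz[ring, , drop = FALSE]))
  }

  # hydrophobic groups: plain-carbon subgraph components of size >= 3
  adj <- adjacency_list(pose)
  plain <- a$element == "C" & !a$aromatic &
    vapply(seq_len(nrow(a)), function(i)
      all(a$element[adj[[i]]] %in% c("C")), logical(1))
  seen <- logical(nrow(a))
  for (i in which(plain)) {
    if (seen[i]) next
    comp <- i; queue <- i; seen[i] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (plain[w] && !seen[w]) {
        seen[w] <- TRUE; comp <- c(comp, w); queue <- c(queue, w)
      }
    }
    if (length(comp) >= 3) add("hydrophobic", colMeans(xyz[comp, , drop = FALSE]))
  }
  if (length(feats) == 0) {
    return(data.frame(ftype = character(), x = numeric(), y = numeric(),
                      z = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, feats)
}

#' Minimum reference count for a prevalence threshold
#'
#' `ceiling(threshold * n_references)`: with 20 references at 70%, a feature
#' must appear in at least 14 binding modes.
#'
#' @param n_references number of reference poses
#' @param prevalence_threshold fraction in (0, 1]
#' @return integer
#' @export
min_reference_count <- function(n_references, prevalence_threshold = 0.70) {
  stopifnot(n_references >= 1, prevalence_threshold > 0, prevalence_threshold <= 1)
  as.integer(ceiling(prevalence_threshold * n_references - 1e-9))
}

#' Build a consensus pharmacophore from reference poses
#'
#' Poses must share one coordinate frame (e.g., all docked into the same
#' site). Features of identical type are clustered across poses by
#' single-linkage with merge distance `merge_radius`; a cluster becomes a
#' model feature iff it draws contributions from at least
#' [min_reference_count()] distinct poses. Cluster centroid becomes the
#' feature position; tolerance is `max(merge_radius, cluster radius)`;
#' prevalence is contributing poses / n_references.
#'
#' @param reference_poses list of `cvs_molecule` with 3D coords (>= 2)
#' @param prevalence_threshold minimum fraction of poses (default 0.70)
#' @param merge_radius single-linkage merge distance, Angstroms (default 1.5)
#' @param min_match features a screened pose must match to pass (default 5)
#' @return a `cvs_pharmacophore`: list(features data.frame, n_references,
#'   prevalence_threshold, min_match)
#' @export
build_pharmacophore <- function(reference_poses, prevalence_threshold = 0.70,
                                merge_radius = 1.5, min_match = 5L) {
  if (length(reference_poses) < 2) stopf("build_pharmacophore: need >= 2 poses")
  n_ref <- length(reference_poses)
  per_pose <- lapply(seq_len(n_ref), function(k) {
    f <- perceive_features(reference_poses[[k]])
    if (nrow(f) > 0) f$pose <- k
    f
  })
  allf <- do.call(rbind, per_pose[vapply(per_pose, nrow, integer(1)) > 0])
  if (is.null(allf) || nrow(allf) == 0) stopf("build_pharmacophore: no features perceived")
  need <- min_reference_count(n_ref, prevalence_threshold)
  out <- list()
  for (ft in unique(allf$ftype)) {
    sub <- allf[allf$ftype == ft, , drop = FALSE]
    cl <- single_linkage_clusters(as.matrix(sub[, c("x", "y", "z")]), merge_radius)
    for (g in unique(cl)) {
      mem <- sub[cl == g, , drop = FALSE]
      n_pose <- length(unique(mem$pose))
      if (n_pose < need) next
      centroid <- colMeans(mem[, c("x", "y", "z")])
      radius <- max(sqrt(rowSums(sweep(as.matrix(mem[, c("x", "y", "z")]), 2, centroid)^2)))
      out[[length(out) + 1]] <- data.frame(
        ftype = ft, x = centroid[1], y = centroid[2], z = centroid[3],
        tolerance = max(merge_radius, radius),
        prevalence = n_pose / n_ref, stringsAsFactors = FALSE)
    }
  }
  features <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(ftype = character(), x = numeric(), y = numeric(), z = numeric(),
               tolerance = numeric(), prevalence = numeric())
  features <- features[order(features$ftype, features$x, features$y, features$z), ,
                       drop = FALSE]
  rownames(features) <- NULL
  structure(list(features = features, n_references = n_ref,
                 prevalence_threshold = prevalence_threshold,
                 min_match = as.integer(min_match)),
            class = "cvs_pharmacophore")
}

# single-linkage clustering with distance cutoff; returns integer labels
single_linkage_clusters <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::dist(xyz), method = "single")
  stats::cutree(hc, h = cutoff)
}

#' Match a candidate pose against a pharmacophore model
#'
#' A model feature is matched when the pose exhibits a perceived feature of
#' the same type within the feature's tolerance. Assignment is one-to-one,
#' greedy nearest-first, ties broken by model-feature order. Passes when at
#' least `model$min_match` features are matched.
#'
#' @param pose `cvs_molecule` with 3D coords, in the model's frame
#' @param model a `cvs_pharmacophore`
#' @return list(n_matched, pass)
#' @export
match_pharmacophore <- function(pose, model) {
  stopifnot(inherits(model, "cvs_pharmacophore"))
  pf <- perceive_features(pose)
  mf <- model$features
  if (nrow(mf) == 0) return(list(n_matched = 0L, pass = 0L >= model$min_match))
  if (nrow(pf) == 0) return(list(n_matched = 0L, pass = FALSE))
  # candidate pairs within tolerance, same type
  cand <- list()
  for (m in seq_len(nrow(mf))) {
    for (p in seq_len(nrow(pf))) {
      if (mf$ftype[m] != pf$ftype[p]) next
      d <- sqrt(sum((c(mf$x[m], mf$y[m], mf$z[m]) - c(pf$x[p], pf$y[p], pf$z[p]))^2))
      if (d <= mf$tolerance[m] + 1e-9) {
        cand[[length(cand) + 1]] <- c(m = m, p = p, d = d)
      }
    }
  }
  n_matched <- 0L
  if (length(cand) > 0) {
    tab <- do.call(rbind, cand)
    tab <- tab[order(tab[, "d"], tab[, "m"]), , drop = FALSE]
    used_m <- logical(nrow(mf)); used_p <- logical(nrow(pf))
    for (k in seq_len(nrow(tab))) {
      m <- tab[k, "m"]; p <- tab[k, "p"]
      if (!used_m[m] && !used_p[p]) {
        used_m[m] <- TRUE; used_p[p] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  list(n_matched = n_matched, pass = n_matched >= model$min_match)
}

#' Serialize / load a pharmacophore model as JSON
#'
#' @param model a `cvs_pharmacophore`
#' @param path JSON path
#' @return invisibly `path` (write) / the model (read)
#' @export
write_pharmacophore <- function(model, path) {
  obj <- list(
    n_references = model$n_references,
    prevalence_threshold = model$prevalence_threshold,
    min_match = model$min_match,
    features = lapply(seq_len(nrow(model$features)), function(i) {
      f <- model$features[i, ]
      list(ftype = f$ftype, centroid = c(f$x, f$y, f$z),
           tolerance = f$tolerance, prevalence = f$prevalence)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  features <- do.call(rbind, lapply(obj$features, function(f) {
    data.frame(ftype = f$ftype, x = f$centroid[[1]], y = f$centroid[[2]],
               z = f$centroid[[3]], tolerance = f$tolerance,
               prevalence = f$prevalence, stringsAsFactors = FALSE)
  }))
  structure(list(features = features, n_references = obj$n_references,
                 prevalence_threshold = obj$prevalence_threshold,
                 min_match = as.integer(obj$min_match)),
            class = "cvs_pharmacophore")
}

#' @export
print.cvs_pharmacophore <- function(x, ...) {
  cat(sprintf("<pharmacophore: %d features from %d references (prevalence >= %.0f%%, pass at >= %d)>\n",
              nrow(x$features), x$n_references, 100 * x$prevalence_threshold, x$min_match))
  invisible(x)
}
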