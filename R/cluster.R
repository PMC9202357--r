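#' Minimal RMSD after optimal rigid superposition
#'
#' Kabsch superposition (optimal rotation and translation) of `b` onto `a`
#' over the selected atoms, delegated to [bio3d::rmsd()].
#'
#' @param a,b `Conformation`s with 1:1 matching selections.
#' @param selection logical mask or integer indices over atoms (default:
#'   backbone N, CA, C, O).
#' @return RMSD in Angstrom.
#' @export
kabschRmsd <- function(a, b, selection = NULL) {
  if (is.null(selection)) selection <- atomMask(a)
  if (is.logical(selection)) {
    if (length(selection) != nrow(a$atoms) ||
        length(selection) != nrow(b$atoms))
      stop("selections differ in atom count between the two conformations")
    selection <- which(selection)
  }
  if (length(selection) && (max(selection) > nrow(a$atoms) ||
                            max(selection) > nrow(b$atoms)))
    stop("selections differ in atom count between the two conformations")
  xa <- coords(a)[selection, , drop = FALSE]
  xb <- coords(b)[selection, , drop = FALSE]
  .pair_rmsd(as.vector(t(xa)), as.vector(t(xb)))
}

# unrounded Kabsch RMSD of two xyz vectors via bio3d superposition
.pair_rmsd <- function(va, vb) {
  inds <- seq_along(va)
  fitted <- bio3d::fit.xyz(va, vb, fixed.inds = inds, mobile.inds = inds)
  sqrt(sum((fitted - va)^2) / (length(va) / 3))
}

# Pairwise RMSD matrix over a model list (all models share one topology).
.rmsd_matrix <- function(models, selection = NULL) {
  n <- length(models)
  if (is.null(selection)) selection <- atomMask(models[[1]])
  if (is.logical(selection)) selection <- which(selection)
  xyz <- t(vapply(models, function(m)
    as.vector(t(coords(m)[selection, , drop = FALSE])),
    numeric(3 * length(selection))))
  mat <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      mat[i, j] <- mat[j, i] <- .pair_rmsd(xyz[i, ], xyz[j, ])
    }
  }
  mat
}

#' Greedy pairwise-RMSD clustering
#'
#' Daura-style neighbor-count clustering: at each round the model with the
#' most neighbors within `cutoff` (ties broken by lower model id) seeds a
#' cluster containing itself and those neighbors, which are then removed.
#' Every model ends up in exactly one cluster (possibly a singleton).
#' Clusters are ranked by decreasing population, ties broken by lower
#' center id; the center is the member with minimal mean RMSD to its
#' co-members.
#'
#' @param models list of `Conformation`s sharing a topology, or a
#'   `ModelSet`.
#' @param cutoff RMSD cutoff in Angstrom (> 0); the cyclization protocol
#'   uses 2.5.
#' @param selection atom selection for the RMSD (default backbone).
#' @return list of `Cluster` objects (members, population, center, rank).
#' @export
clusterByRmsd <- function(models, cutoff = 2.5, selection = NULL) {
  if (inherits(models, "ModelSet")) models <- models$models
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!length(models)) stop("no models to cluster")
  n <- length(models)
  mat <- .rmsd_matrix(models, selection)
  unassigned <- seq_len(n)
  clusters <- list()
  while (length(unassigned)) {
    nb <- lapply(unassigned, function(i)
      unassigned[mat[i, unassigned] <= cutoff])   # includes i itself
    sizes <- lengths(nb)
    pick <- which.max(sizes)                       # ties: lowest id first
    members <- sort(nb[[pick]])
    if (length(members) == 1L) {
      center <- members
    } else {
      mean_rmsd <- vapply(members, function(i)
        mean(mat[i, setdiff(members, i)]), numeric(1))
      center <- members[which.min(mean_rmsd)]      # ties: lowest id
    }
    clusters[[length(clusters) + 1L]] <-
      list(members = members, population = length(members),
           center = center)
    unassigned <- setdiff(unassigned, members)
  }
  pop <- vapply(clusters, `[[`, numeric(1), "population")
  ctr <- vapply(clusters, `[[`, numeric(1), "center")
  ord <- order(-pop, ctr)
  clusters <- clusters[ord]
  for (k in seq_along(clusters)) {
    clusters[[k]]$rank <- k
    class(clusters[[k]]) <- "Cluster"
  }
  clusters
}

#' @export
print.Cluster <- function(x, ...) {
  cat(sprintf("Cluster rank %d: %d members, center %d\n",
              x$rank, x$population, x$center))
  invisible(x)
}

#' Representatives of the most populated clusters
#'
#' Returns the centers of the top `max_n` clusters in rank order (fewer if
#' fewer clusters were formed), as an `Ensemble`.
#'
#' @param clusters result of [clusterByRmsd()].
#' @param models the model list (or `ModelSet`) that was clustered.
#' @param max_n maximum number of representatives (default 10).
#' @return an `Ensemble` with `members` and a `table` of
#'   (cluster_rank, model, population).
#' @export
selectRepresentatives <- function(clusters, models, max_n = 10) {
  if (inherits(models, "ModelSet")) models <- models$models
  take <- clusters[seq_len(min(max_n, length(clusters)))]
  members <- lapply(take, function(cl) models[[cl$center]])
  table <- data.frame(
    cluster_rank = vapply(take, `[[`, numeric(1), "rank"),
    model = vapply(take, `[[`, numeric(1), "center"),
    population = vapply(take, `[[`, numeric(1), "population"))
  structure(list(members = members, table = table,
                 spec = models[[1]]$spec, max_size = max_n),
            class = "Ensemble")
}

#' Write a cluster report
#' @param clusters result of [clusterByRmsd()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
writeClusterTable <- function(clusters, path) {
  df <- data.frame(
    rank = vapply(clusters, `[[`, numeric(1), "rank"),
    population = vapply(clusters, `[[`, numeric(1), "population"),
    center = vapply(clusters, `[[`, numeric(1), "center"),
    members = vapply(clusters, function(cl)
      paste(cl$members, collapse = ","), character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
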