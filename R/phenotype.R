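#' Pool and subsample QC-passed cells per disease class
#'
#' Draws `n_per_class` cells without replacement, uniformly from the
#' union of each class's ROI cell tables (5000 per class by default),
#' and pools them for clustering.
#'
#' @param tables_by_class named list (one element per disease class) of
#'   lists of QC-passed [cell_table()]s.
#' @param n_per_class cells to draw from each class.
#' @param seed integer seed; identical seed gives an identical sample.
#' @param allow_smaller if `TRUE`, a class pool smaller than
#'   `n_per_class` is taken whole instead of raising an error.
#' @return a data.frame with columns `class`, `roi_id`, `cell_id`,
#'   `area_um2`, `mean_intensity` (plus `truth_phenotype` when present in
#'   the inputs).
#' @export
subsample_cells <- function(tables_by_class, n_per_class = 5000, seed = 1L,
                            allow_smaller = FALSE) {
  pools <- lapply(names(tables_by_class), function(cls) {
    tabs <- tables_by_class[[cls]]
    if (is_cell_table(tabs)) tabs <- list(tabs)
    parts <- lapply(tabs, function(tb) {
      out <- data.frame(class = rep(cls, nrow(tb)),
                        roi_id = rep(attr(tb, "roi_id"), nrow(tb)),
                        cell_id = tb$cell_id,
                        area_um2 = tb$area_um2,
                        mean_intensity = tb$mean_intensity,
                        stringsAsFactors = FALSE)
      out$truth_phenotype <- if ("truth_phenotype" %in% names(tb))
        tb$truth_phenotype else NA_character_
      out
    })
    do.call(rbind, parts)
  })
  names(pools) <- names(tables_by_class)
  with_seed(seed, {
    sampled <- lapply(names(pools), function(cls) {
      pool <- pools[[cls]]
      n <- n_per_class
      if (nrow(pool) < n) {
        if (!allow_smaller)
          stop(sprintf("class %s has %d < %d cells", cls, nrow(pool), n),
               call. = FALSE)
        n <- nrow(pool)
      }
      pool[sort(sample.int(nrow(pool), n)), , drop = FALSE]
    })
    out <- do.call(rbind, sampled)
    rownames(out) <- NULL
    out
  })
}

# Standardization helper: z-scale (area_um2, mean_intensity) with a
# scaler fitted on the clustering sample.
#' @noRd
fit_scaler <- function(sample) {
  center <- c(area_um2 = mean(sample$area_um2),
              intensity = mean(sample$mean_intensity))
  scale <- c(area_um2 = stats::sd(sample$area_um2),
             intensity = stats::sd(sample$mean_intensity))
  if (any(!is.finite(scale)) || any(scale == 0))
    stop("degenerate sample: zero variance in a clustering feature",
         call. = FALSE)
  list(center = center, scale = scale)
}

#' @noRd
apply_scaler <- function(scaler, area_um2, mean_intensity) {
  if (any(scaler$scale <= 0))
    stop("invalid scaler: non-positive feature SD", call. = FALSE)
  cbind(size_z = (area_um2 - scaler$center[["area_um2"]]) /
          scaler$scale[["area_um2"]],
        intensity_z = (mean_intensity - scaler$center[["intensity"]]) /
          scaler$scale[["intensity"]])
}

#' Spectral clustering of sampled cells on (size, intensity)
#'
#' Standardizes nuclear area and mean intensity on the sample, builds a
#' symmetrized k-nearest-neighbor affinity graph (k = 10), embeds it
#' with the top eigenvectors of the normalized affinity
#' (`D^-1/2 A D^-1/2`, the normalized-Laplacian embedding), row-normalizes
#' the embedding, and partitions it with seeded k-means (10 restarts).
#'
#' @param sample a data.frame from [subsample_cells()] (needs `area_um2`
#'   and `mean_intensity`).
#' @param k number of clusters (default 3).
#' @param seed integer seed controlling the embedding solver and k-means.
#' @param knn_k affinity-graph neighbor count.
#' @return a list of class `phenotype_clustering`: `cluster` (integer
#'   vector), `scaler`, `centroids_z` (k x 2 matrix of standardized
#'   cluster means), `sample`, `seed`.
#' @export
cluster_phenotypes <- function(sample, k = 3, seed = 1L, knn_k = 10L) {
  n <- nrow(sample)
  if (n < k) stop("sample smaller than the number of clusters", call. = FALSE)
  scaler <- fit_scaler(sample)
  x <- apply_scaler(scaler, sample$area_um2, sample$mean_intensity)
  cl <- with_seed(seed, {
    nn <- knn_indices(x, min(knn_k, n - 1L))
    el <- cbind(rep(seq_len(n), ncol(nn)), as.vector(nn))
    g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
    emb <- igraph::embed_laplacian_matrix(
      g, no = k, type = "DAD", options = list(maxiter = 500000))$X
    rn <- sqrt(rowSums(emb^2))
    rn[rn == 0] <- 1
    emb <- emb / rn
    stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100)$cluster
  })
  centroids_z <- t(vapply(seq_len(k), function(ci)
    colMeans(x[cl == ci, , drop = FALSE]), numeric(2)))
  colnames(centroids_z) <- c("size_z", "intensity_z")
  structure(list(cluster = cl, scaler = scaler, centroids_z = centroids_z,
                 sample = sample, seed = seed),
            class = "phenotype_clustering")
}

#' Name clusters as CLL-like, aCLL-like, and RT-like
#'
#' The cluster with the largest mean standardized size is RT-like; of
#' the remaining two, the one with lower mean intensity is CLL-like and
#' the other aCLL-like -- matching the observed ordering of the three
#' phenotypes (small/dim, small/bright, large).
#'
#' @param centroids_z a 3 x 2 matrix of cluster means with columns
#'   `size_z`, `intensity_z` (rows in cluster-index order).
#' @return `name_map`: a character vector of phenotype names indexed by
#'   cluster. An exact tie in a deciding statistic raises an error.
#' @export
assign_phenotype_names <- function(centroids_z) {
  if (nrow(centroids_z) != 3)
    stop("phenotype naming is defined for exactly 3 clusters", call. = FALSE)
  size <- centroids_z[, "size_z"]
  if (sum(size == max(size)) > 1)
    stop("ambiguous phenotypes: tied mean cluster size", call. = FALSE)
  rt <- which.max(size)
  rest <- setdiff(seq_len(3), rt)
  ints <- centroids_z[rest, "intensity_z"]
  if (ints[1] == ints[2])
    stop("ambiguous phenotypes: tied mean cluster intensity", call. = FALSE)
  cll <- rest[which.min(ints)]
  acll <- setdiff(rest, cll)
  map <- character(3)
  map[cll] <- "CLL-like"; map[acll] <- "aCLL-like"; map[rt] <- "RT-like"
  map
}

#' Fit the phenotype label propagator
#'
#' A multinomial logistic regression (ridge-penalized at a weak fixed
#' strength `lambda = 1/n`, deterministic coordinate-descent fit) on
#' standardized (size, intensity), trained on the clustered sample with
#' its named phenotype labels.
#'
#' @param x_z standardized feature matrix (columns `size_z`,
#'   `intensity_z`).
#' @param labels phenotype names per row.
#' @return a coefficient matrix with rows `(Intercept)`, `size_z`,
#'   `intensity_z` and one column per phenotype in canonical order.
#' @export
fit_propagator <- function(x_z, labels) {
  present <- phenotype_names()[phenotype_names() %in% unique(labels)]
  if (length(present) < 2)
    stop("propagator needs at least 2 distinct phenotype labels",
         call. = FALSE)
  y <- factor(labels, levels = present)
  fit <- glmnet::glmnet(x_z, y, family = "multinomial", alpha = 0,
                        lambda = 1 / nrow(x_z), standardize = FALSE,
                        thresh = 1e-10)
  cf <- stats::coef(fit)
  beta <- matrix(0, nrow = 3, ncol = length(phenotype_names()),
                 dimnames = list(c("(Intercept)", "size_z", "intensity_z"),
                                 phenotype_names()))
  # absent phenotypes keep -Inf score so they are never predicted
  beta[1, setdiff(phenotype_names(), present)] <- -Inf
  for (ph in present) beta[, ph] <- as.numeric(cf[[ph]])
  beta
}

#' @noRd
propagator_probs <- function(beta, x_z) {
  scores <- cbind(1, x_z) %*% beta
  scores <- scores - apply(scores, 1, max)
  e <- exp(scores)
  e / rowSums(e)
}

#' Fit the full phenotype model on a training cohort
#'
#' Subsamples cells per class, runs spectral clustering, names the
#' clusters, and fits the label propagator. The returned model labels
#' any QC-passed cell table via [propagate_labels()] /
#' `predict(model, table)`.
#'
#' @param tables_by_class named list of QC-passed [cell_table()]s per
#'   disease class (see [subsample_cells()]).
#' @param n_per_class,seed,knn_k,allow_smaller passed to the stages.
#' @return an object of class `phenotype_model`: `scaler`, `name_map`,
#'   `coefficients`, `cluster` (sample assignments, named), `sample`,
#'   `seed`.
#' @export
fit_phenotype_model <- function(tables_by_class, n_per_class = 5000,
                                seed = 1L, knn_k = 10L,
                                allow_smaller = FALSE) {
  sample <- subsample_cells(tables_by_class, n_per_class, seed,
                            allow_smaller = allow_smaller)
  clus <- cluster_phenotypes(sample, k = 3, seed = seed, knn_k = knn_k)
  name_map <- assign_phenotype_names(clus$centroids_z)
  labels <- name_map[clus$cluster]
  x_z <- apply_scaler(clus$scaler, sample$area_um2, sample$mean_intensity)
  beta <- fit_propagator(x_z, labels)
  structure(list(scaler = clus$scaler, name_map = name_map,
                 coefficients = beta, cluster = labels, sample = sample,
                 seed = seed),
            class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("<phenotype_model> spectral clustering + multinomial LR propagator\n")
  cat(sprintf("clustering sample: %d cells, seed %d\n",
              length(x$cluster), x$seed))
  print(table(phenotype = x$cluster))
  cat("scaler center:", sprintf("%.3f", x$scaler$center), "\n")
  cat("scaler scale: ", sprintf("%.3f", x$scaler$scale), "\n")
  invisible(x)
}

#' Propagate phenotype labels to a cell table
#'
#' Standardizes each cell's (size, intensity) with the model's scaler,
#' computes multinomial class probabilities, and assigns the argmax
#' phenotype (probability ties break to the earlier phenotype in the
#' fixed order CLL-like < aCLL-like < RT-like).
#'
#' @param model a [fit_phenotype_model()] result.
#' @param tab a QC-passed [cell_table()].
#' @return `tab` with a `phenotype` column added.
#' @export
propagate_labels <- function(model, tab) {
  stopifnot(inherits(model, "phenotype_model"))
  out <- tab
  if (nrow(tab) == 0) {
    out$phenotype <- character(0)
    return(rewrap_cell_table(out, tab))
  }
  x_z <- apply_scaler(model$scaler, tab$area_um2, tab$mean_intensity)
  probs <- propagator_probs(model$coefficients, x_z)
  out$phenotype <- phenotype_names()[max.col(probs, ties.method = "first")]
  rewrap_cell_table(out, tab)
}

#' @rdname propagate_labels
#' @param object a `phenotype_model`.
#' @param newdata a [cell_table()].
#' @param ... unused.
#' @export
predict.phenotype_model <- function(object, newdata, ...) {
  propagate_labels(object, newdata)
}

#' Serialize a phenotype model to JSON and back
#'
#' Stores the scaler, propagator coefficients, name map, and seed; the
#' clustering sample itself is not serialized.
#'
#' @param model a `phenotype_model`.
#' @param path file path.
#' @return `write_phenotype_model` returns `path` invisibly;
#'   `read_phenotype_model` returns a `phenotype_model` (without the
#'   `sample`/`cluster` fields).
#' @export
write_phenotype_model <- function(model, path) {
  beta <- model$coefficients
  beta[!is.finite(beta)] <- NA  # JSON has no -Inf; restore on read
  jsonlite::write_json(list(
    scaler = list(center = as.list(model$scaler$center),
                  scale = as.list(model$scaler$scale)),
    name_map = model$name_map,
    coefficients = as.data.frame(beta),
    seed = model$seed), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_phenotype_model
#' @export
read_phenotype_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- as.matrix(raw$coefficients)
  beta[is.na(beta)] <- -Inf
  rownames(beta) <- c("(Intercept)", "size_z", "intensity_z")
  colnames(beta) <- phenotype_names()
  structure(list(
    scaler = list(center = unlist(raw$scaler$center),
                  scale = unlist(raw$scaler$scale)),
    name_map = raw$name_map,
    coefficients = beta,
    seed = as.integer(raw$seed)), class = "phenotype_model")
}
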