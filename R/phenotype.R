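# UMAP projection of latent embeddings and the responsive-vs-resistant
# phenotype separation report.

#' Project embeddings to 2-D with UMAP
#'
#' Runs uniform manifold approximation and projection on the latent matrix
#' via the `umap-learn` Python library (the `python` executable must be on
#' the PATH with `umap-learn` installed). The projection is deterministic
#' given `seed` and is intended for visualization only; separation statistics
#' are always computed in the full latent space.
#'
#' @param embeddings An `embedding_set` or a numeric matrix (n x d).
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed Integer random state.
#' @return For a matrix input, an n x 2 coordinate matrix; for an
#'   `embedding_set`, the same set with `$umap` filled in.
#' @export
embed_umap <- function(embeddings, n_neighbors = 15, min_dist = 0.1,
                       seed = 42L) {
  is_set <- inherits(embeddings, "embedding_set")
  m <- if (is_set) embeddings$matrix else as.matrix(embeddings)
  if (nrow(m) < n_neighbors + 1) {
    stop_input("need at least n_neighbors + 1 = %d rows, got %d",
               n_neighbors + 1, nrow(m))
  }
  py <- Sys.which("python")
  if (py == "") stop_input("`python` (with umap-learn) not found on PATH")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(m, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- paste(
    "import sys, warnings, numpy as np",
    "warnings.filterwarnings('ignore')",
    "import umap",
    "fin, fout, nn, md, seed = sys.argv[1:6]",
    "X = np.loadtxt(fin, delimiter=',', ndmin=2)",
    "emb = umap.UMAP(n_neighbors=int(nn), min_dist=float(md),",
    "                random_state=int(seed), n_jobs=1).fit_transform(X)",
    "np.savetxt(fout, emb, delimiter=',')",
    sep = "\n")
  res <- system2(py, c("-c", shQuote(script), fin, fout,
                       as.character(n_neighbors), as.character(min_dist),
                       as.character(seed)),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop_input("UMAP projection failed:\n%s", paste(res, collapse = "\n"))
  }
  coords <- as.matrix(utils::read.table(fout, sep = ","))
  dimnames(coords) <- list(NULL, c("UMAP1", "UMAP2"))
  if (is_set) {
    embeddings$umap <- coords
    embeddings
  } else {
    coords
  }
}

#' Mean silhouette width of phase labels in latent space
#'
#' @param m Numeric matrix of embeddings.
#' @param labels Class labels, one per row.
#' @return Mean silhouette width, or `NA` if degenerate (identical points or
#'   a single class).
#' @export
latent_silhouette <- function(m, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) return(NA_real_)
  d <- stats::dist(m)
  if (max(d) == 0) return(NA_real_)
  sil <- cluster::silhouette(as.integer(droplevels(labels)), d)
  mean(sil[, "sil_width"])
}

#' Phenotype separation report for labeled embeddings
#'
#' Quantifies how well the treatment-responsive and treatment-resistant
#' classes separate: the mean silhouette width of the phase labels in the
#' full latent space, per-class means of the normalized CK/CD45/DAPI
#' intensities and cell area, and direction flags for the expected marker
#' shifts (resistant cells higher in CK, responsive cells higher in CD45).
#'
#' @param embedding_set An `embedding_set` with at least two phase classes of
#'   at least `min_per_class` crops each.
#' @param min_per_class Minimum class size.
#' @return A list of class `separation_report`: `silhouette`, `degenerate`,
#'   `class_means` (data frame), `ck_resistant_minus_responsive`,
#'   `cd45_responsive_minus_resistant`, and logical direction flags
#'   `ck_up_in_resistant`, `cd45_up_in_responsive`.
#' @export
phenotype_report <- function(embedding_set, min_per_class = 5) {
  stopifnot(inherits(embedding_set, "embedding_set"))
  phase <- embedding_set$phase
  tab <- table(phase)
  if (length(tab) < 2) {
    stop_input("phenotype report needs at least 2 labeled classes, got %d",
               length(tab))
  }
  if (any(tab < min_per_class)) {
    stop_input("every class needs at least %d crops (got: %s)", min_per_class,
               paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  sil <- latent_silhouette(embedding_set$matrix, phase)
  feat <- embedding_set$features
  cm <- do.call(rbind, lapply(split(feat, phase), function(d) {
    data.frame(mean_CK = mean(d$mean_CK), mean_CD45 = mean(d$mean_CD45),
               mean_DAPI = mean(d$mean_DAPI), area_px = mean(d$area_px))
  }))
  cm <- cbind(phase = rownames(cm), cm, row.names = NULL)
  dir_ck <- dir_cd45 <- NA_real_
  if (all(c("responsive", "resistant") %in% cm$phase)) {
    res <- cm[cm$phase == "resistant", ]
    rsp <- cm[cm$phase == "responsive", ]
    dir_ck <- res$mean_CK - rsp$mean_CK
    dir_cd45 <- rsp$mean_CD45 - res$mean_CD45
  }
  structure(list(
    silhouette = sil,
    degenerate = is.na(sil),
    class_means = cm,
    ck_resistant_minus_responsive = dir_ck,
    cd45_responsive_minus_resistant = dir_cd45,
    ck_up_in_resistant = if (is.na(dir_ck)) NA else dir_ck > 0,
    cd45_up_in_responsive = if (is.na(dir_cd45)) NA else dir_cd45 > 0
  ), class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report>\n")
  if (x$degenerate) {
    cat("  degenerate embedding (identical points or single class)\n")
  } else {
    cat(sprintf("  latent silhouette: %.3f\n", x$silhouette))
  }
  print(x$class_means, row.names = FALSE)
  if (!is.na(x$ck_resistant_minus_responsive)) {
    cat(sprintf("  CK  resistant - responsive: %+.3f (%s)\n",
                x$ck_resistant_minus_responsive,
                if (x$ck_up_in_resistant) "expected direction" else "unexpected"))
    cat(sprintf("  CD45 responsive - resistant: %+.3f (%s)\n",
                x$cd45_responsive_minus_resistant,
                if (x$cd45_up_in_responsive) "expected direction" else "unexpected"))
  }
  invisible(x)
}
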