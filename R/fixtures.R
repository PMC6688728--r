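#' Load cortical region centroids
#'
#' Reads a CSV with columns `region, x_mm, y_mm, z_mm`. The packaged default
#' is a synthetic 78-region cortical layout (39 regions per hemisphere on an
#' ellipsoidal cortical shell, MNI-like mm coordinates) that stands in for a
#' cortical atlas parcellation; any user-supplied CSV with the same columns
#' can be used instead.
#'
#' @param path CSV path; default the packaged synthetic layout.
#' @return Data frame with rownames = region names and columns
#'   `x_mm, y_mm, z_mm`.
#' @export
load_centroids <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_centroids_78.csv",
                        package = "dfcsim", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop("centroid CSV must have columns region, x_mm, y_mm, z_mm",
         call. = FALSE)
  }
  out <- df[, c("x_mm", "y_mm", "z_mm")]
  rownames(out) <- df$region
  out
}

#' Load resting-state network templates
#'
#' Combines region centroids with four binary node masks (DMN, SMN, FPN,
#' visual) read from a CSV with columns `region, DMN, SMN, FPN, VIS` (0/1).
#' The packaged masks are synthetic, literature-guided node sets over the
#' synthetic 78-region layout: they place the default-mode, sensorimotor,
#' frontoparietal and visual networks at anatomically plausible positions
#' but are not derived from empirical fMRI maps.
#'
#' @param masks_path CSV path for the masks; default the packaged file.
#' @param centroids_path CSV path for the centroids; default the packaged
#'   layout.
#' @return An object of class `rsn_templates`: list with `centroids`
#'   (matrix `N x 3`) and `masks` (named list of node index vectors).
#' @export
load_rsn_templates <- function(masks_path = NULL, centroids_path = NULL) {
  cent <- load_centroids(centroids_path)
  if (is.null(masks_path)) {
    masks_path <- system.file("extdata", "synthetic_rsn_masks_78.csv",
                              package = "dfcsim", mustWork = TRUE)
  }
  df <- utils::read.csv(masks_path, stringsAsFactors = FALSE)
  need <- c("region", "DMN", "SMN", "FPN", "VIS")
  if (!all(need %in% names(df))) {
    stop("mask CSV must have columns region, DMN, SMN, FPN, VIS",
         call. = FALSE)
  }
  if (!identical(df$region, rownames(cent))) {
    stop("mask and centroid region lists disagree", call. = FALSE)
  }
  masks <- lapply(c(DMN = "DMN", SMN = "SMN", FPN = "FPN", VIS = "VIS"),
                  function(k) which(df[[k]] == 1L))
  if (any(vapply(masks, length, integer(1)) == 0L)) {
    stop("every mask must be non-empty", call. = FALSE)
  }
  structure(
    list(centroids = as.matrix(cent), masks = masks),
    class = "rsn_templates"
  )
}

#' @export
print.rsn_templates <- function(x, ...) {
  sizes <- vapply(x$masks, length, integer(1))
  cat(sprintf("<rsn_templates> %d regions; masks: %s\n",
              nrow(x$centroids),
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' Build templates directly from a centroid matrix and mask list
#'
#' Programmatic constructor used for scaled-down simulations and tests.
#'
#' @param centroids Numeric matrix `N x 3` (mm).
#' @param masks Named list of integer node-index vectors.
#' @return An `rsn_templates` object.
#' @export
rsn_templates <- function(centroids, masks) {
  centroids <- as.matrix(centroids)
  if (any(vapply(masks, length, integer(1)) == 0L)) {
    stop("every mask must be non-empty", call. = FALSE)
  }
  if (any(unlist(masks) < 1L) || any(unlist(masks) > nrow(centroids))) {
    stop("mask indices out of range", call. = FALSE)
  }
  structure(list(centroids = centroids, masks = masks),
            class = "rsn_templates")
}
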