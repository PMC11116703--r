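#' Write a raw movie as multi-page TIFF with a JSON sidecar
#'
#' Frames go to a 32-bit float multi-page TIFF (intensities rescaled to
#' `[0, 1]` by the stored `scale`); landmarks, fps, ids and the state
#' segment table go to `<path>.json`.
#'
#' @param movie a `raw_movie`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$frames)
  mx <- max(movie$frames)
  pages <- lapply(seq_len(d[3]), function(t) movie$frames[, , t] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(fps = movie$fps, bregma = movie$bregma, lambda = movie$lambda,
               subject_id = movie$subject_id, session_id = movie$session_id,
               scale = mx, segments = movie$segments)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raw movie written by [write_movie()]
#'
#' @param path TIFF path with its `.json` sidecar alongside.
#' @return A `raw_movie`.
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) *
    meta$scale
  raw_movie(frames, fps = meta$fps, bregma = unlist(meta$bregma),
            lambda = unlist(meta$lambda),
            segments = as.data.frame(meta$segments),
            subject_id = meta$subject_id, session_id = meta$session_id)
}

#' Write an atlas as a TIFF label image plus JSON legend
#'
#' @param atlas a `wf_atlas`.
#' @param path output TIFF path; the legend goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  tiff::writeTIFF(atlas$labels / 255, path, bits.per.sample = 8L)
  jsonlite::write_json(list(legend = as.list(atlas$legend),
                            bregma = atlas$bregma, lambda = atlas$lambda,
                            midline_cols = atlas$midline_cols),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param path TIFF label-image path with its `.json` legend alongside.
#' @return A `wf_atlas`.
#' @export
read_atlas <- function(path) {
  labels <- round(tiff::readTIFF(path) * 255)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(labels = matrix(as.integer(labels), nrow(labels)),
                 legend = unlist(meta$legend), bregma = unlist(meta$bregma),
                 lambda = unlist(meta$lambda),
                 midline_cols = as.integer(meta$midline_cols),
                 mask = labels > 0),
            class = "wf_atlas")
}
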