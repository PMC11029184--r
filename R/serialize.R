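#' Save and load fitted models as JSON
#'
#' The static risk model, the normality model and the fusion parameters are
#' all plain-parameter objects; they serialise to human-readable JSON so a
#' fitted system can be versioned and applied elsewhere.
#'
#' @param model an `rs1_model`, `novelty_model` or `fusion_parameters`.
#' @param path file to write / read.
#' @return `write_model()`: the path, invisibly; `read_model()`: the model.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1]
  payload <- unclass(model)
  if (kind == "rs1_model") {
    # named numeric vectors must serialise as JSON objects, not arrays
    payload$coefficients <- as.list(model$coefficients)
    payload$preprocessing <- lapply(model$preprocessing, function(v) {
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
    })
  }
  if (kind == "novelty_model") {
    payload$point_channels <- model$channels
    payload$points <- lapply(seq_len(nrow(model$points)),
                             function(i) as.numeric(model$points[i, ]))
  }
  jsonlite::write_json(list(kind = kind, payload = payload), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$payload
  switch(x$kind,
    rs1_model = {
      named_num <- function(v) {
        u <- unlist(v)
        if (is.null(u)) setNames(numeric(0), character(0)) else u
      }
      p$coefficients <- named_num(p$coefficients)
      p$preprocessing <- lapply(p$preprocessing, unlist)
      for (f in c("medians", "centers", "scales")) {
        p$preprocessing[[f]] <- named_num(p$preprocessing[[f]])
      }
      for (f in c("features", "dropped")) {
        p$preprocessing[[f]] <- as.character(unlist(p$preprocessing[[f]]))
      }
      structure(p, class = "rs1_model")
    },
    novelty_model = {
      pts <- if (is.matrix(p$points)) p$points else do.call(rbind, p$points)
      colnames(pts) <- p$point_channels
      p$points <- pts
      p$point_channels <- NULL
      p$centers <- unlist(p$centers)
      p$scales <- unlist(p$scales)
      p$bandwidths <- unlist(p$bandwidths)
      p$calibration <- as.numeric(p$calibration)
      structure(p, class = "novelty_model")
    },
    fusion_parameters = fusion_parameters(p$beta, p$t_max),
    stop("unknown model kind '", x$kind, "'"))
}
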