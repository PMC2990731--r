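#' Save a fitted model to a portable JSON file
#'
#' Single-file, versioned, plain-text serialization for PLS models,
#' perceptrons and perceptron ensembles. Numeric fields are written at
#' full precision so predictions from a reloaded model are identical.
#'
#' @param model a \code{pls_model}, \code{perceptron_model} or
#'   \code{ensemble_model}.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  type <- if (inherits(model, "pls_model")) "pls"
          else if (inherits(model, "perceptron_model")) "perceptron"
          else if (inherits(model, "ensemble_model")) "ensemble"
          else stop("unsupported model class")
  m <- unclass(model)
  if (type == "ensemble") m$members <- lapply(m$members, unclass)
  payload <- list(format = "mhcqsar-model", version = 1L, type = type,
                  model = m)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by \code{\link{write_model}}
#'
#' @param path path to the JSON model file.
#' @return the model with its class restored.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  if (!identical(payload$format, "mhcqsar-model")) {
    stop("not a model file: ", path)
  }
  m <- payload$model
  fix_mats <- function(m) {
    for (f in c("weights", "x_loadings", "scores", "input_weights",
                "x_range")) {
      if (!is.null(m[[f]]) && !is.matrix(m[[f]])) {
        m[[f]] <- as.matrix(m[[f]])
      }
    }
    m
  }
  switch(payload$type,
         pls = structure(fix_mats(m), class = "pls_model"),
         perceptron = structure(fix_mats(m), class = "perceptron_model"),
         ensemble = {
           m$members <- lapply(m$members, function(mm)
             structure(fix_mats(mm), class = "perceptron_model"))
           if (is.matrix(m$membership)) {
             m$membership <- lapply(seq_len(nrow(m$membership)),
                                    function(i) m$membership[i, ])
           }
           structure(m, class = "ensemble_model")
         },
         stop("unknown model type: ", payload$type))
}
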