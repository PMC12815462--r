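# Text serialization for solver weights and trained transfer models.

#' Write solver weights as a flat numeric vector with a text header
#'
#' Decoder-generated and directly trained weights share this format.
#'
#' @param w a `solver_weights`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_solver_weights <- function(w, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  a <- w$arch
  writeLines(c("#solver-weights v1",
               paste("#arch", a$I, a$Q, a$K, a$M %||% NA, a$S %||% NA),
               fmt_num(w$theta)), con, sep = "\n")
  invisible(path)
}

#' Read solver weights written by [write_solver_weights()]
#' @param path file path.
#' @return a `solver_weights`.
#' @export
read_solver_weights <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "#solver-weights v1") stop_eidt("not a solver weight file")
  hf <- strsplit(lines[2], " ")[[1]][-1]
  hd <- as.numeric(replace(hf, hf == "NA", NA))
  arch <- if (!is.na(hd[4])) solver_arch(hd[4])
          else accumulator_arch(K = hd[3], Q = hd[2], S = hd[5])
  solver_weights(as.numeric(lines[-(1:2)]), arch)
}

#' Save a trained transfer model as a JSON bundle
#'
#' Architecture descriptors, configuration, the full parameter vector, and
#' the training log are stored in one JSON file (full numeric precision).
#' Evidence sources of perceptual models are closures and are not stored;
#' supply them again when loading.
#'
#' @param model an `eidt_model` or `perc_eidt_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eidt_model <- function(model, path) {
  bundle <- list(format = "eidt-model v1", task = model$task,
                 source = model$source, target = model$target,
                 latent_dim = model$latent_dim, Ie = model$Ie, R = model$R,
                 head_sizes = model$head_sizes,
                 arch = model$arch_tgt[c("M", "I", "Q", "K", "S")],
                 config = unclass(model$config), par = model$par,
                 log = model$log)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a transfer model saved by [write_eidt_model()]
#'
#' @param path file path.
#' @param sources evidence sources (required for perceptual models).
#' @return an `eidt_model` / `perc_eidt_model`.
#' @export
read_eidt_model <- function(path, sources = NULL) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$format, "eidt-model v1")) stop_eidt("not a model bundle")
  config <- structure(b$config, class = "eidt_config")
  if (b$task == "mdp") {
    model <- new_eidt_model(b$source, b$target,
                            setNames(b$arch$M, b$target), config)
  } else {
    if (is.null(sources)) stop_eidt("perceptual models need their evidence sources")
    model <- new_perc_model(b$source, b$target, sources, config)
  }
  model$par <- as.numeric(b$par)
  model$log <- b$log
  model
}
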