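#' Montages: channel-to-role maps
#'
#' A montage is a named character vector mapping channel label to role
#' (`"scalp"` or `"mastoid"`). The pipeline requires Cz, Pz, C3 and C4 plus
#' exactly two mastoids. `standard_montage("basic")` is the compact 8-channel
#' synthesis montage (Cz, FCz, CPz, Pz, C3, C4 + M1, M2); `"minimal"` keeps
#' only the six required channels;
#' `standard_montage("full64")` is a 64-scalp-channel 10-10 layout plus the
#' two mastoids, matching a 64-electrode recording setup.
#'
#' @param name `"basic"`, `"minimal"` (just the six required channels) or
#'   `"full64"`.
#' @return named character vector of roles, class `montage`.
#' @export
standard_montage <- function(name = c("basic", "minimal", "full64")) {
  name <- match.arg(name)
  scalp <- if (name == "basic") {
    c("Cz", "FCz", "CPz", "Pz", "C3", "C4")
  } else if (name == "minimal") {
    c("Cz", "Pz", "C3", "C4")
  } else {
    c("Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
      "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
      "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
      "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
      "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
      "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
      "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz", "Fpz")
  }
  m <- c(stats::setNames(rep("scalp", length(scalp)), scalp),
         M1 = "mastoid", M2 = "mastoid")
  structure(m, class = "montage")
}

REQUIRED_CHANNELS <- c("Cz", "Pz", "C3", "C4")

validate_montage <- function(montage) {
  if (is.null(names(montage)) || anyDuplicated(names(montage))) {
    stopf("montage channel labels must be unique and named")
  }
  if (!all(montage %in% c("scalp", "mastoid"))) {
    stopf("montage roles must be 'scalp' or 'mastoid'")
  }
  missing <- setdiff(REQUIRED_CHANNELS, names(montage))
  if (length(missing)) {
    stopf("montage is missing required channel(s): %s",
          paste(missing, collapse = ", "))
  }
  n_mast <- sum(montage == "mastoid")
  if (n_mast != 2) {
    stopf("montage must tag exactly 2 mastoid channels (found %d)", n_mast)
  }
  invisible(montage)
}

mastoid_channels <- function(montage) names(montage)[montage == "mastoid"]
scalp_channels <- function(montage) names(montage)[montage == "scalp"]

#' Read / write a montage as a JSON channel-to-role map
#'
#' @param montage a montage (named character vector of roles).
#' @param path file path.
#' @return `read_montage` returns a `montage`; `write_montage` its path,
#'   invisibly.
#' @export
write_montage <- function(montage, path) {
  jsonlite::write_json(as.list(unclass(montage)), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  x <- jsonlite::read_json(path)
  m <- structure(vapply(x, as.character, character(1)), class = "montage")
  validate_montage(m)
  m
}
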