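#' Read a field image from PNG or TIFF
#'
#' Reads the file, converts to 8-bit grayscale with [toGray8()], and wraps
#' it in a [CytoField-class].
#'
#' @param path PNG or TIFF file.
#' @param fieldIndex,specimenId field provenance.
#' @return a [CytoField-class].
#' @export
readFieldImage <- function(path, fieldIndex = 1L, specimenId = "specimen") {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  # readers return unit-range values
  CytoField(toGray8(img, maxValue = 1), fieldIndex = fieldIndex,
            specimenId = specimenId)
}

#' Write a field image (or its mask) as 8-bit grayscale PNG
#'
#' @param field a [CytoField-class].
#' @param path output PNG path.
#' @param what `"gray"` (default) or `"mask"` (foreground white).
#' @return the path, invisibly.
#' @export
writeFieldImage <- function(field, path, what = c("gray", "mask")) {
  what <- match.arg(what)
  img <- switch(what,
    gray = field@gray / 255,
    mask = {
      if (!length(field@mask)) stop("field has no mask")
      field@mask * 1
    }
  )
  png::writePNG(img, path)
  invisible(path)
}

#' Write / read the cohort table as CSV
#'
#' One row per patient: `patient_id`, `age`, `cytology`, `histology`,
#' `time_months`, `event`, followed by the specimen-level morphometry
#' columns.
#'
#' @param x a [CytometryExperiment-class].
#' @param path CSV path.
#' @return `writeCohortCSV`: the path, invisibly. `readCohortCSV`: a
#'   [CytometryExperiment-class].
#' @export
writeCohortCSV <- function(x, path) {
  cd <- as.data.frame(colData(x))
  out <- cbind(patient_id = colnames(x), cd[, c("age", "cytology",
               "histology", "time_months", "event")],
               as.data.frame(t(morphometry(x))))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  metaCols <- c("patient_id", "age", "cytology", "histology",
                "time_months", "event")
  featCols <- setdiff(colnames(df), metaCols)
  feats <- t(as.matrix(df[, featCols, drop = FALSE]))
  colnames(feats) <- df$patient_id
  CytometryExperiment(feats, df[, c("age", "cytology", "histology",
                                    "time_months", "event")])
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [cohortConfig()] or [studyConfig()] list.
#' @param path YAML path.
#' @return `writeConfigYAML`: the path, invisibly. `readConfigYAML`: the
#'   configuration list (matrices restored).
#' @export
writeConfigYAML <- function(config, path) {
  ser <- function(x) {
    if (is.matrix(x)) {
      list(.matrix = TRUE, rows = as.list(rownames(x)),
           cols = as.list(colnames(x)), data = as.list(as.vector(t(x))))
    } else if (is.list(x)) {
      lapply(x, ser)
    } else if (!is.null(names(x))) {
      as.list(x)  # named atomic vectors become YAML maps, keeping names
    } else {
      x
    }
  }
  yaml::write_yaml(ser(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname writeConfigYAML
#' @param template a configuration to inherit defaults from (entries in
#'   the file override it).
#' @export
readConfigYAML <- function(path, template = cohortConfig()) {
  restore <- function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      m <- matrix(unlist(x$data), nrow = length(x$rows), byrow = TRUE,
                  dimnames = list(unlist(x$rows), unlist(x$cols)))
      return(m)
    }
    if (is.list(x)) return(lapply(x, restore))
    x
  }
  obj <- restore(yaml::read_yaml(path))
  # named numeric vectors flatten to lists in YAML; restore them
  fix <- function(tmpl, val) {
    if (is.null(val)) return(tmpl)
    if (is.list(val) && !is.null(tmpl) && is.numeric(tmpl) && length(tmpl) > 1) {
      nm <- names(val)
      if (is.null(nm) && length(val) == length(tmpl)) nm <- names(tmpl)
      return(setNames(unlist(val), nm))
    }
    if (is.list(val) && is.list(tmpl)) {
      for (nm in names(val)) tmpl[[nm]] <- fix(tmpl[[nm]], val[[nm]])
      return(tmpl)
    }
    val
  }
  out <- fix(unclass(template), obj)
  class(out) <- class(template)
  out
}
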