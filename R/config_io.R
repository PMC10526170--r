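# Flat sectioned key = value configuration files. Numbers are written
# with %.17g so every double round-trips bit-exactly; no installed R
# package parses this TOML-like dialect, hence the ~60 lines here.

fmt_value <- function(v) {
  if (is.null(v)) return("auto")
  if (is.logical(v)) return(tolower(as.character(v)))
  if (is.character(v)) return(v)
  paste(sprintf("%.17g", v), collapse = ", ")
}

parse_value <- function(s) {
  s <- trimws(s)
  if (identical(s, "auto")) return(NULL)
  if (s %in% c("true", "false")) return(identical(s, "true"))
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  n <- suppressWarnings(as.numeric(parts))
  if (length(n) && !anyNA(n)) return(n)
  s
}

#' Write a configuration to a sectioned text file
#'
#' @param cfg [hdc_config()]
#' @param path output file
#' @return `path`, invisibly
#' @seealso [read_config()]
#' @export
write_config <- function(cfg, path) {
  secs <- c("params", "boundary", "initial", "grid", "hybrid", "synth")
  names(secs) <- c("parameters", "boundary", "initial", "grid", "hybrid",
                   "synth")
  lines <- character()
  for (i in seq_along(secs)) {
    sec <- cfg[[secs[[i]]]]
    lines <- c(lines, sprintf("[%s]", names(secs)[i]))
    for (key in names(sec))
      lines <- c(lines, sprintf("%s = %s", key, fmt_value(sec[[key]])))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a model configuration
#'
#' Reads a sectioned `key = value` file (sections `parameters`,
#' `boundary`, `initial`, `grid`, `hybrid`, `synth`; all optional).
#' Unspecified keys take the package defaults, which are the published
#' parameter-table values where those exist. A `dose_mg_per_ml` key in the
#' `boundary` section is converted to the molar `m0` via
#' [dose_to_molar()] using `parameters.molar_mass`. All validation
#' failures are collected and reported together, naming the offending
#' keys.
#'
#' @param path configuration file
#' @return a validated [hdc_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  sec <- NA_character_
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      sec <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(out[[sec]])) out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.na(sec)) stop("config: key outside any [section]: ", ln,
                           call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[sec]][[key]] <- parse_value(val)
    } else {
      stop("config: cannot parse line: ", ln, call. = FALSE)
    }
  }

  take <- function(section, ctor, rename = NULL, drop = character()) {
    given <- out[[section]]
    if (is.null(given)) given <- list()
    for (nm in names(rename))
      names(given)[names(given) == nm] <- rename[[nm]]
    given <- given[!(names(given) %in% drop)]
    known <- names(formals(ctor))
    bad <- setdiff(names(given), known)
    if (length(bad))
      stop(sprintf("config: unknown key(s) in [%s]: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    do.call(ctor, given)
  }

  params <- take("parameters", hdc_params)
  bsec <- out[["boundary"]]
  if (!is.null(bsec$dose_mg_per_ml)) {
    dose <- bsec$dose_mg_per_ml
    if (!is.null(bsec$m0))
      stop("config: [boundary] gives both m0 and dose_mg_per_ml",
           call. = FALSE)
    out[["boundary"]]$m0 <- dose_to_molar(dose, params$molar_mass)
    out[["boundary"]]$dose_mg_per_ml <- NULL
  }
  boundary <- take("boundary", hdc_boundary)
  initial <- take("initial", hdc_initial, drop = "m_init")
  grid <- take("grid", hdc_grid)
  hybrid <- take("hybrid", hdc_hybrid)
  synth <- take("synth", synth_spec)
  hdc_config(params = params, boundary = boundary, initial = initial,
             grid = grid, hybrid = hybrid, synth = synth)
}
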