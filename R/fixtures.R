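#' Path to a bundled example dataset
#'
#' The package ships the printed tables of its Madrid pilot day as small
#' CSV fixtures: `"trace_day.csv"` (the tracking-app trace),
#' `"exposure_day.csv"` (the integrated indoor/outdoor exposure table),
#' `"routes_day.csv"` (per-route integrated PM2.5 intensities) and
#' `"pollutant_units.csv"` (pollutants and units per data source).
#' Called without arguments, lists the available files.
#'
#' @param file fixture file name.
#' @return full path to the file (or the list of file names).
#' @export
#' @examples
#' pape_example()
#' head(read.csv(pape_example("trace_day.csv"), check.names = FALSE))
pape_example <- function(file = NULL) {
  if (is.null(file))
    return(setdiff(dir(system.file("extdata", package = "pape")), "MANIFEST.md5"))
  p <- system.file("extdata", file, package = "pape")
  if (p == "") stop("no such example file: ", file)
  p
}

#' Verify the bundled fixtures against their checksum manifest
#'
#' @return `TRUE` invisibly; stops if any checksum mismatches.
#' @export
verify_fixtures <- function() {
  man_path <- system.file("extdata", "MANIFEST.md5", package = "pape")
  man <- read.table(man_path, header = FALSE, col.names = c("md5", "file"),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(man))) {
    p <- system.file("extdata", man$file[i], package = "pape")
    got <- unname(tools::md5sum(p))
    if (!identical(got, man$md5[i]))
      stop("fixture checksum mismatch for ", man$file[i])
  }
  invisible(TRUE)
}
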