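#' Load a packaged paired-measurement table
#'
#' The package ships the per-patient SUV measurement tables of the
#' ten-patient method-comparison study it reproduces: `"table2"` holds
#' organ SUVmax from the commercial MIM workflow versus whole-organ
#' contours ("contour"); `"table3"` holds organ SUVmean from MIM, a
#' single 1.2 cm VOI ("one VOI"), and whole-organ contours; `"table4"`
#' holds per-patient lesion TLG at the 40% and 50% SUVmax thresholds.
#'
#' @param name one of `"table2"`, `"table3"`, `"table4"`.
#' @return For table2/table3 a [paired_measurement_table()]; for table4 a
#'   plain `data.frame` with columns `patient`, `location`, `tlg_40`,
#'   `tlg_50`.
#' @examples
#' t2 <- load_table_fixture("table2")
#' subset(as.data.frame(t2), patient == 1 & organ == "Breast_R")
#' @export
load_table_fixture <- function(name) {
  files <- c(table2 = "table2_suvmax.csv",
             table3 = "table3_suvmean.csv",
             table4 = "table4_tlg.csv")
  if (length(name) != 1L || !name %in% names(files)) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(names(files), collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", files[[name]], package = "petquant",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (name == "table4") return(df)
  paired_measurement_table(df)
}
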