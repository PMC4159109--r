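#' Load a printed-table fixture
#'
#' The package ships the published experimental tables as plain CSV
#' fixtures: `"table1"` -- exposure conditions and times to rupture for the
#' 18 rupture-prediction trials (non-ruptured trials encoded as missing
#' time with `ruptured = FALSE`); `"table4"` -- paired rupture times for the
#' 10 suppression trials (censored at 300 s) with vessel type; and
#' `"calibration"` -- the six-point drive-voltage calibration.
#'
#' @param name One of `"table1"`, `"table4"`, `"calibration"`.
#' @return A tibble.
#' @examples
#' load_table_fixture("table4")
#' @export
load_table_fixture <- function(name = c("table1", "table4", "calibration")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "pcdrupture", mustWork = TRUE)
  df <- as_tibble(utils::read.csv(path))
  if (name == "table1") {
    df$ruptured <- !is.na(df$time_to_rupture_s)
  }
  df
}
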