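#' Published water-balance and parameter tables
#'
#' Loads the packaged CSV copies of the field study's printed tables: the
#' weekly soil water balance per variety (`weekly_balance`), the seasonal
#' balance components (`seasonal_balance`) and the measured crop parameter
#' table (`parameters`). Values are stored digit-for-digit as printed; note
#' that the weekly table's `dS` column carries the opposite sign to
#' `Qo - Qi` (a decrease in storage is printed positive-side-down), and the
#' printed solar extinction coefficient for the hybrid (0.31) differs in the
#' last digit from the absorptance conversion of its `k_par` (0.304).
#'
#' @return List with data.frames `weekly_balance`, `seasonal_balance`,
#'   `parameters`.
#' @export
load_fixture_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "milletswb",
                                  mustWork = TRUE)
  wb <- utils::read.csv(path("table1_weekly_balance.csv"), stringsAsFactors = FALSE)
  wb$date <- as.Date(wb$date)
  list(weekly_balance = wb,
       seasonal_balance = utils::read.csv(path("table2_seasonal.csv"),
                                          stringsAsFactors = FALSE),
       parameters = utils::read.csv(path("table3_parameters.csv"),
                                    stringsAsFactors = FALSE))
}
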