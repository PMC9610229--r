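# Packaged drug-property and formulation tables, plus the implant
# configurations of the worked examples. The three property tables are the
# package's reference data: physicochemical properties of the 7 training
# drugs, the drug-in-excipient saturation solubilities (12 excipients x 8
# drug columns, mean and SD kept separately; EFdA appears once per supplier
# source), and the 4 validation drugs.

.FIXTURE_MD5 <- c(
  table1_training_drugs.csv = "c5d0a1af45f8859a23f10c1fc19a3e16",
  table2_excipient_solubility.csv = "8f2e751c6a3be354d6fde479997e31c4",
  table3_validation_drugs.csv = "891ba8cdc162303ffa1865f283d78bc7",
  implant_configs.csv = "126313513ebd2fcc187aefe32387ae67")

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "dkimplant")
  if (p == "") stop("integrity error: fixture ", file, " not found", call. = FALSE)
  p
}

#' Load the packaged reference tables
#'
#' Reads and validates the packaged CSVs: `table1` (7 training drugs with
#' MW, CsP, pKa, logP), `table2` (saturation solubility CsE of each drug in
#' 12 excipients, mean and SD; the two EFdA supplier sources are distinct
#' rows), `table3` (4 validation drugs), and `configs` (the implant
#' geometries and loadings of the worked release examples). File checksums
#' and sentinel values are verified; any mismatch raises an integrity
#' error.
#'
#' @param verify Check fixture md5 checksums (default `TRUE`).
#' @return A `"fixture_set"` list with `table1`, `table2`, `table3`,
#'   `configs`.
#' @examples
#' fx <- load_fixtures()
#' subset(fx$table1, drug == "FTC")
#' @export
load_fixtures <- function(verify = TRUE) {
  files <- names(.FIXTURE_MD5)
  paths <- vapply(files, .fixture_path, character(1))
  if (verify) {
    got <- tools::md5sum(paths)
    bad <- files[got != .FIXTURE_MD5]
    if (length(bad))
      stop("integrity error: fixture checksum mismatch: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  table1 <- utils::read.csv(paths[["table1_training_drugs.csv"]],
                            stringsAsFactors = FALSE)
  table2 <- utils::read.csv(paths[["table2_excipient_solubility.csv"]],
                            stringsAsFactors = FALSE)
  table3 <- utils::read.csv(paths[["table3_validation_drugs.csv"]],
                            stringsAsFactors = FALSE)
  configs <- utils::read.csv(paths[["implant_configs.csv"]],
                             stringsAsFactors = FALSE)
  ok <- nrow(table1) == 7L && nrow(table3) == 4L && nrow(table2) == 96L &&
    isTRUE(all.equal(table1$csp_mg_ml[table1$drug == "FTC"], 165.6)) &&
    isTRUE(all.equal(table3$mw_da[table3$drug == "ABC"], 286.3)) &&
    isTRUE(all.equal(
      table2$cse_mg_ml[table2$drug == "LNG" & table2$excipient == "PEG_300"],
      3.68))
  if (!ok) stop("integrity error: fixture content failed validation",
                call. = FALSE)
  structure(list(table1 = table1, table2 = table2, table3 = table3,
                 configs = configs),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf(
    "Fixture set: %d training drugs, %d validation drugs, %d solubility rows, %d implant configs\n",
    nrow(x$table1), nrow(x$table3), nrow(x$table2), nrow(x$configs)))
  invisible(x)
}

#' Look up a drug-in-excipient solubility
#'
#' @param fixtures A [load_fixtures()] result.
#' @param drug Drug label as in the tables (e.g. `"FTC"`).
#' @param excipient Excipient label (e.g. `"Castor Oil"`).
#' @param efda_source `"Wuxi"` or `"Pharmaron"`, used only for EFdA.
#' @return The mean CsE in mg/mL.
#' @export
lookup_cse <- function(fixtures, drug, excipient, efda_source = "Wuxi") {
  stopifnot(inherits(fixtures, "fixture_set"))
  t2 <- fixtures$table2
  hit <- t2$drug == drug & t2$excipient == excipient
  if (drug == "EFdA") hit <- hit & t2$source %in% efda_source
  if (sum(hit) != 1L)
    stop("input error: unknown drug/excipient combination: ",
         drug, " / ", excipient, call. = FALSE)
  t2$cse_mg_ml[hit]
}

#' All drug x excipient property rows for a drug panel
#'
#' Joins a property table (training `table1` or validation `table3`) with
#' the excipient solubility table into the flat schema consumed by
#' [predict_log10_dk()] and [fit_qspr()]: one row per drug x excipient
#' combination with `mw_da`, `csp_mg_ml`, `pka`, `logp`, `cse_mg_ml`.
#' Only drugs present in both tables are returned; for EFdA the requested
#' supplier source is used. The excipient-solubility table covers the
#' training drugs only, so the validation grid is empty — validation-drug
#' predictions need user-supplied CsE values.
#'
#' @inheritParams lookup_cse
#' @param which `"training"` (table1, default) or `"validation"` (table3).
#' @return Data frame of property rows.
#' @export
property_grid <- function(fixtures, which = c("training", "validation"),
                          efda_source = "Wuxi") {
  stopifnot(inherits(fixtures, "fixture_set"))
  which <- match.arg(which)
  props <- if (which == "training") fixtures$table1 else fixtures$table3
  t2 <- fixtures$table2
  t2 <- t2[t2$drug != "EFdA" | t2$source %in% efda_source, ]
  out <- merge(props, t2[, c("drug", "excipient", "cse_mg_ml")], by = "drug")
  out <- out[order(match(out$drug, props$drug), out$excipient), ]
  rownames(out) <- NULL
  out
}
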