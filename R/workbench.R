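# End-to-end demonstration workbench and MS identification table.

#' MRM / exact-mass identification table
#'
#' Builds the identification table for the case-study analytes. Instrument
#' transitions (unit-resolution precursor/product settings) are fixed
#' constants for reticuline (330.10 > 192.00, positive mode) and
#' DHPAA-oxime (168.10 > 151.15, positive mode); the `exact_mh` column is
#' the computed monoisotopic `[M+H]+` for cross-checking and is reported
#' for every analyte, transition or not.
#'
#' @param analytes A data frame with columns `name` and `formula`. The
#'   default covers reticuline and DHPAA-oxime.
#' @return A data frame with columns `name`, `formula`, `precursor_mz`,
#'   `product_mz`, `polarity` (instrument settings, `NA` where none is
#'   defined) and `exact_mh`, `nominal_mh` (computed values).
#' @examples
#' mrm_table()
#' @export
mrm_table <- function(analytes = data.frame(
                        name = c("reticuline", "DHPAA-oxime"),
                        formula = c("C19H23NO4", "C8H9NO3"),
                        stringsAsFactors = FALSE)) {
  if (!all(c("name", "formula") %in% names(analytes))) {
    stop("analytes need columns name, formula", call. = FALSE)
  }
  no_formula <- !nzchar(analytes$formula) | is.na(analytes$formula)
  if (any(no_formula)) {
    stop("analyte(s) without a formula: ",
         paste(analytes$name[no_formula], collapse = ", "), call. = FALSE)
  }
  instrument <- data.frame(
    name = c("reticuline", "DHPAA-oxime"),
    precursor_mz = c(330.10, 168.10),
    product_mz = c(192.00, 151.15),
    polarity = c("+", "+"), stringsAsFactors = FALSE)
  out <- merge(analytes, instrument, by = "name", all.x = TRUE, sort = FALSE)
  out$exact_mh <- vapply(out$formula, monoisotopic_mz, numeric(1),
                         adduct = "+H")
  out$nominal_mh <- vapply(out$formula, nominal_mz, integer(1),
                           adduct = "+H")
  out[order(match(out$name, analytes$name)),
      c("name", "formula", "precursor_mz", "product_mz", "polarity",
        "exact_mh", "nominal_mh")]
}

#' Run the packaged end-to-end demonstration
#'
#' Builds the demonstration knowledge base, mines pathways from L-DOPA
#' (C00355) to DHPAA (C04043), verifies the aldoxime route against the
#' held-out DHPAA-oxime structure (the putative intermediate vector must
#' equal the featurization of the real structure), checks the two
#' delta-transfer identities, and assembles the m/z identification table.
#'
#' @param seed Integer seed (knowledge-base decoys and search subsampling).
#' @param dir Optional output directory; when given, `report.json` (with
#'   the resolved configuration echoed for provenance) and the knowledge
#'   base fixtures are written there.
#' @param decoys Include decoys in the knowledge base.
#' @return The demo report (a list), invisibly self-describing; stages:
#'   `ranking`, `oxime_route`, `delta_transfer`, `mrm`.
#' @examples
#' report <- run_demo(42)
#' report$ranking$top_n_steps  # 2
#' @export
run_demo <- function(seed = 42L, dir = NULL, decoys = TRUE) {
  config <- list(format = "pathminer/1", seed = as.integer(seed),
                 decoys = decoys, source = "C00355", target = "C04043",
                 k_max = 3L, theta = 0.7, c_max = 1L,
                 iterations = 200L, subset_size = 20L)

  kb <- build_demo_kb(seed = seed, dir = if (is.null(dir)) NULL else
                        file.path(dir, "kb"), decoys = decoys)
  res <- mine(kb, config$source, config$target, k_max = config$k_max,
              theta = config$theta, c_max = config$c_max,
              iterations = config$iterations,
              subset_size = config$subset_size, seed = seed)
  if (length(res$pathways) == 0L) {
    stop("demo stage 'mine': no pathway found", call. = FALSE)
  }
  summary_df <- as.data.frame(res)

  # locate the aldoxime route (tyrosine N-monooxygenase then aldehyde
  # oxidase) and verify its putative intermediate against the holdout
  oxime_idx <- which(vapply(res$pathways, function(p) {
    identical(p$steps$ec, c("1.14.14.36", "1.2.3.1"))
  }, logical(1)))
  if (length(oxime_idx) == 0L) {
    stop("demo stage 'oxime_route': aldoxime route not found", call. = FALSE)
  }
  oxp <- res$pathways[[oxime_idx[1]]]
  holdout <- kb$vectors["X00001", ]
  oxime_ok <- all(oxp$intermediates[[1]] == holdout)

  transfer <- list(
    aldoxime_formation =
      all(kb$vectors["C00355", ] +
            (kb$vectors["C04353", ] - kb$vectors["C00082", ]) == holdout),
    aldoxime_to_aldehyde =
      all(holdout +
            (kb$vectors["C07113", ] - kb$vectors["CID5464950", ]) ==
            kb$vectors["C04043", ])
  )

  report <- list(
    format = "pathminer/1",
    config = config,
    ranking = list(
      n_pathways = length(res$pathways),
      top_n_steps = nrow(res$pathways[[1]]$steps),
      top_score = res$pathways[[1]]$score,
      table = summary_df
    ),
    oxime_route = list(
      rank = oxime_idx[1],
      step_scores = oxp$steps$step_score,
      score = oxp$score,
      intermediate_matches_holdout = oxime_ok,
      step1_exceeds_step2 =
        oxp$steps$step_score[1] > oxp$steps$step_score[2]
    ),
    delta_transfer = transfer,
    mrm = mrm_table()
  )
  for (stage in c("oxime_route")) {
    if (!isTRUE(report$oxime_route$intermediate_matches_holdout)) {
      stop("demo stage 'oxime_route': intermediate does not match holdout",
           call. = FALSE)
    }
  }
  if (!all(unlist(transfer))) {
    stop("demo stage 'delta_transfer': identity check failed", call. = FALSE)
  }

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
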