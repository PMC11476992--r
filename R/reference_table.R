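#' Reference fold-change table of growth-related vitreous DEPs
#'
#' Published per-eye SWATH fold changes (days 14, 21 and 28 vs day 7) for the
#' 14 growth-related differentially expressed proteins of the chick vitreous
#' emmetropization study this package is built around, together with the
#' reported "AVE FC +/- SD" summaries (values as printed, 2 decimal places).
#' Bundled as a worked reference input: re-deriving the summaries with
#' [average_fc()] and the directions with [classify_direction()] exercises
#' the bilateral-concordance machinery against known output.
#'
#' @return data.frame with one row per protein: `accession`, `protein_name`,
#'   `gene`, and for each contrast day d in {14, 21, 28} the columns
#'   `fc_od_<d>`, `fc_os_<d>` (per-eye fold change vs day 7), `ave_<d>` and
#'   `sd_<d>` (printed summary).
#' @export
vitreous_dep_reference <- function() {
  txt <- "
accession|protein_name|gene|fc_od_14|fc_os_14|ave_14|sd_14|fc_od_21|fc_os_21|ave_21|sd_21|fc_od_28|fc_os_28|ave_28|sd_28
R4GLH0|IGFBP N-terminal domain-containing protein|ESM1|4.08|3.02|3.55|0.75|4.53|3.51|4.02|0.72|6.73|5.09|5.91|1.16
Q4ADJ6|Ovotransferrin|TFEW|4.09|2.30|3.20|1.27|1.81|2.26|2.04|0.32|9.39|5.11|7.25|3.03
P84407|Alpha-fetoprotein|AFP|0.01|0.40|0.21|0.28|0.01|0.01|0.01|0.00|0.01|0.02|0.02|0.01
P79995|Cadherin-10|CDH10|0.46|0.12|0.29|0.24|0.43|0.39|0.41|0.03|0.40|0.35|0.38|0.04
P24503|Cadherin-4|CDH4|0.31|0.32|0.32|0.01|0.34|0.43|0.39|0.06|0.37|0.40|0.39|0.02
E1C3A7|Cadherin-22|CDH22|0.41|0.14|0.28|0.19|0.34|0.41|0.38|0.05|0.33|0.30|0.32|0.02
Q8AWW2|Cadherin-7|NA|0.33|0.38|0.36|0.04|0.39|0.32|0.36|0.05|0.32|0.34|0.33|0.01
Q8QGH3|Cadherin-20|CDH20|0.47|0.61|0.54|0.10|0.44|0.44|0.44|0.00|0.45|0.53|0.49|0.06
Q9W6E1|Neurocan core protein|NA|0.23|0.48|0.36|0.18|0.21|0.20|0.21|0.01|0.17|0.19|0.18|0.01
Q90953|Versican core protein|VCAN|0.33|0.59|0.46|0.18|0.20|0.25|0.23|0.04|0.19|0.19|0.19|0.00
O93574|Reelin|RELN|0.41|0.58|0.50|0.12|0.45|0.48|0.47|0.02|0.42|0.47|0.45|0.04
F1NSJ1|Contactin-2|CNTN2|0.51|0.23|0.37|0.20|0.44|0.46|0.45|0.01|0.52|0.52|0.52|0.00
P35331|Neuronal cell adhesion molecule|NRCAM|0.32|0.57|0.45|0.18|0.59|0.56|0.58|0.02|0.67|0.50|0.59|0.12
Q90610|Neogenin|NEO1|0.65|0.39|0.52|0.18|0.54|0.55|0.55|0.00|0.67|0.62|0.65|0.04
"
  df <- utils::read.delim(text = txt, sep = "|", stringsAsFactors = FALSE,
                          na.strings = "NA")
  df
}

#' Long view of the reference fold-change table
#'
#' One row per protein per contrast day, convenient for re-deriving every
#' summary cell.
#'
#' @return data.frame with columns accession, gene, day, fc_od, fc_os,
#'   ave_printed, sd_printed.
#' @export
vitreous_dep_reference_long <- function() {
  wide <- vitreous_dep_reference()
  do.call(rbind, lapply(c(14L, 21L, 28L), function(d) {
    data.frame(accession = wide$accession, gene = wide$gene, day = d,
               fc_od = wide[[paste0("fc_od_", d)]],
               fc_os = wide[[paste0("fc_os_", d)]],
               ave_printed = wide[[paste0("ave_", d)]],
               sd_printed = wide[[paste0("sd_", d)]],
               stringsAsFactors = FALSE)
  }))
}
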