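AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Theoretical maximum exchangeable amide hydrogens of a peptide
#'
#' Counts backbone amides that can carry deuterium: peptide length minus the
#' two N-terminal residues (which back-exchange too fast to observe) minus
#' any proline at position 3 onward (prolines have no amide hydrogen).
#'
#' @param sequence One-letter peptide sequence(s) (standard residues only).
#' @return Integer vector of counts (>= 0).
#' @export
max_exchangeable <- function(sequence) {
  vapply(sequence, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    if (length(ch) < 1) stop("empty peptide sequence")
    bad <- setdiff(ch, AA1)
    if (length(bad) > 0)
      stop("non-standard residue letter(s): ", paste(bad, collapse = ", "))
    n_pro <- if (length(ch) >= 3) sum(ch[3:length(ch)] == "P") else 0L
    max(0L, length(ch) - 2L - n_pro)
  }, integer(1), USE.NAMES = FALSE)
}

#' Percent deuterium uptake of a peptide measurement
#'
#' 100 x observed mass shift / (maximum exchangeable amides x D2O fraction).
#' The labelling buffer is not pure D2O, so the theoretical ceiling is scaled
#' by the deuterium fraction of the incubation (default 0.917). No
#' back-exchange correction is applied.
#'
#' @param mass_shift Observed centroid mass shift(s) in Da.
#' @param max_exch Maximum exchangeable amides (from [max_exchangeable()]).
#' @param d2o_fraction Deuterium fraction of the labelling buffer.
#' @return Percent uptake (can exceed 100 in noisy data).
#' @export
percent_uptake <- function(mass_shift, max_exch, d2o_fraction = 0.917) {
  if (any(max_exch <= 0))
    stop("percent uptake undefined for peptides with no exchangeable amides")
  100 * mass_shift / (max_exch * d2o_fraction)
}

check_hdx_records <- function(records) {
  need <- c("construct", "start_res", "end_res", "sequence", "timepoint_s",
            "replicate", "mass_shift_da")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("HDX records missing column(s): ", paste(miss, collapse = ", "))
  bad <- nchar(records$sequence) != records$end_res - records$start_res + 1
  if (any(bad))
    stop("peptide sequence length disagrees with residue bounds in row(s): ",
         paste(head(which(bad), 5), collapse = ", "))
  records
}

#' Summarise replicate HDX uptake measurements
#'
#' Computes percent uptake per record and aggregates replicates per
#' (construct, peptide, timepoint) cell: mean, sample SD (n-1 denominator; a
#' single replicate reports SD 0 and is flagged).
#'
#' @param records data.frame with columns `construct`, `start_res`,
#'   `end_res`, `sequence`, `timepoint_s`, `replicate`, `mass_shift_da`.
#' @param d2o_fraction Deuterium fraction of the labelling buffer.
#' @return data.frame with `construct`, `start_res`, `end_res`, `sequence`,
#'   `timepoint_s`, `max_exch`, `mean_uptake`, `sd_uptake`, `n_rep`,
#'   `single_replicate`.
#' @export
hdx_summarize <- function(records, d2o_fraction = 0.917) {
  records <- check_hdx_records(records)
  records$max_exch <- max_exchangeable(records$sequence)
  records$uptake <- percent_uptake(records$mass_shift_da, records$max_exch,
                                   d2o_fraction)
  key <- interaction(records$construct, records$start_res, records$end_res,
                     records$sequence, records$timepoint_s, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    data.frame(construct = g$construct[1], start_res = g$start_res[1],
               end_res = g$end_res[1], sequence = g$sequence[1],
               timepoint_s = g$timepoint_s[1], max_exch = g$max_exch[1],
               mean_uptake = mean(g$uptake),
               sd_uptake = if (nrow(g) > 1) sd(g$uptake) else 0,
               n_rep = nrow(g), single_replicate = nrow(g) == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$construct, out$start_res, out$end_res,
                   out$timepoint_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential HDX between two constructs over common peptides
#'
#' Joins two summarised uptake tables on peptide identity (start, end,
#' sequence) and timepoint, and reports the uptake difference
#' (mutant - reference) per common cell. Peptides present on only one side
#' (e.g. because a mutation changed the peptide sequence or the digestion
#' pattern) are returned separately, never silently dropped; a construct pair
#' with no common peptides yields an explicit empty comparison.
#'
#' @param wt,mutant Summaries from [hdx_summarize()] (one construct each).
#' @return List with `comparison` (data.frame with `mean_uptake_wt`,
#'   `mean_uptake_mut`, `delta` = mut - wt, `sd_wt`, `sd_mut`),
#'   `uncomparable_wt` and `uncomparable_mut` (peptide/timepoint rows with no
#'   partner).
#' @export
hdx_differential <- function(wt, mutant) {
  key <- function(d) paste(d$start_res, d$end_res, d$sequence,
                           d$timepoint_s, sep = "|")
  kw <- key(wt); km <- key(mutant)
  common <- intersect(kw, km)
  w <- wt[match(common, kw), , drop = FALSE]
  m <- mutant[match(common, km), , drop = FALSE]
  comparison <- data.frame(
    start_res = w$start_res, end_res = w$end_res, sequence = w$sequence,
    timepoint_s = w$timepoint_s,
    mean_uptake_wt = w$mean_uptake, mean_uptake_mut = m$mean_uptake,
    delta = m$mean_uptake - w$mean_uptake,
    sd_wt = w$sd_uptake, sd_mut = m$sd_uptake,
    stringsAsFactors = FALSE
  )
  rownames(comparison) <- NULL
  list(comparison = comparison,
       uncomparable_wt = wt[!(kw %in% common), , drop = FALSE],
       uncomparable_mut = mutant[!(km %in% common), , drop = FALSE])
}

# mean per-residue value over covering peptide ranges; sentinel for uncovered
residue_cover_values <- function(res_seq, starts, ends, values,
                                 sentinel = -1) {
  vapply(res_seq, function(r) {
    hit <- starts <= r & ends >= r
    if (!any(hit)) sentinel else mean(values[hit])
  }, numeric(1))
}

#' Paint per-residue HDX uptake onto a structure's B-factors
#'
#' Each residue's B-factor is set to the mean uptake of all peptides covering
#' it at the chosen construct and timepoint; residues covered by no peptide
#' get the sentinel value (-1). Peptide bounds refer to the structure's
#' author numbering.
#'
#' @param s A `structure3d`.
#' @param summary A summary from [hdx_summarize()].
#' @param construct Construct to paint.
#' @param timepoint_s Timepoint to paint.
#' @param chain Restrict painting to one chain (`NULL`: all).
#' @param sentinel Value for uncovered residues.
#' @return The structure with B-factors replaced.
#' @export
paint_uptake <- function(s, summary, construct, timepoint_s, chain = NULL,
                         sentinel = -1) {
  sub <- summary[summary$construct == construct &
                   summary$timepoint_s == timepoint_s, , drop = FALSE]
  paint_residues(s, sub$start_res, sub$end_res, sub$mean_uptake, chain,
                 sentinel)
}

paint_residues <- function(s, starts, ends, values, chain = NULL,
                           sentinel = -1) {
  vals <- residue_cover_values(s$atoms$res_seq, starts, ends, values,
                               sentinel)
  sel <- if (is.null(chain)) rep(TRUE, nrow(s$atoms))
  else s$atoms$chain %in% chain
  s$atoms$bfactor[sel] <- round(vals[sel], 2)
  s
}
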