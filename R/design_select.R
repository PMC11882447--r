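#' Design selection thresholds
#'
#' Thresholds of the three selection criteria, exposed as configuration:
#' designs destabilizing both states beyond `unfold_threshold` REU are
#' discarded as likely unfolded; `c1_threshold` flags a loss of signalling
#' (criterion 1, `ddG_apo` above threshold); `c2_threshold` flags
#' insufficient static-switchable hydration (criterion 2, count below
#' threshold); `reference_count` anchors the Hyd_low/Hyd_high
#' classification.
#'
#' @param unfold_threshold REU (default 8).
#' @param c1_threshold REU (default 5).
#' @param c2_threshold count (default 18).
#' @param reference_count count (default 20).
#' @return A `selection_config` list.
#' @export
selection_config <- function(unfold_threshold = 8, c1_threshold = 5,
                             c2_threshold = 18L, reference_count = 20L) {
  stopifnot(is.finite(unfold_threshold), is.finite(c1_threshold),
            c2_threshold >= 0)
  structure(list(unfold_threshold = unfold_threshold,
                 c1_threshold = c1_threshold,
                 c2_threshold = c2_threshold,
                 reference_count = reference_count),
            class = "selection_config")
}

#' Discard designs destabilizing both receptor states
#'
#' A design whose `dG_inactive` AND `dG_active` (relative to the reference)
#' both exceed the unfolding threshold destabilizes both conformations and
#' would likely unfold; such designs are discarded before the selection
#' criteria are applied. Single-state destabilization is retained (it is
#' the design lever of criterion 1).
#'
#' @param designs data.frame with columns `design_id`, `dG_inactive`,
#'   `dG_active` (REU).
#' @param config a [selection_config].
#' @return list with `retained` and `discarded` (the latter with a `reason`
#'   column).
#' @export
filter_unfolded <- function(designs, config = selection_config()) {
  need <- c("design_id", "dG_inactive", "dG_active")
  miss <- setdiff(need, names(designs))
  if (length(miss)) stop("design table missing columns: ",
                         paste(miss, collapse = ", "))
  bad_energy <- !is.finite(designs$dG_inactive) | !is.finite(designs$dG_active)
  unfolded <- !bad_energy &
    designs$dG_inactive > config$unfold_threshold &
    designs$dG_active > config$unfold_threshold
  discarded <- designs[bad_energy | unfolded, , drop = FALSE]
  if (nrow(discarded))
    discarded$reason <- ifelse(bad_energy[bad_energy | unfolded],
                               "missing_energy", "unfolded")
  else discarded$reason <- character()
  retained <- designs[!(bad_energy | unfolded), , drop = FALSE]
  rownames(retained) <- rownames(discarded) <- NULL
  list(retained = retained, discarded = discarded)
}

#' Apply selection criteria 1 and 2 and classify hydration
#'
#' Adds flag columns: `c1_loss` when `ddG_apo` exceeds the criterion-1
#' threshold (active state too destabilized for basal signalling) and
#' `c2_fail` when the static-switchable water-mediated count falls below
#' the criterion-2 threshold; the hydration `class` is assigned against
#' the reference count.
#'
#' @param designs data.frame with `ddG_apo` and `n_static_switchable`
#'   columns (typically `filter_unfolded(...)$retained`).
#' @param config a [selection_config].
#' @return `designs` with logical `c1_loss`, `c2_fail` and character
#'   `class` columns appended.
#' @export
apply_criteria <- function(designs, config = selection_config()) {
  designs$c1_loss <- designs$ddG_apo > config$c1_threshold
  designs$c2_fail <- designs$n_static_switchable < config$c2_threshold
  designs$class <- vapply(designs$n_static_switchable, classify_hydration,
                          character(1), reference = config$reference_count)
  designs
}

#' Rank designs for experimental validation
#'
#' Unflagged designs come first, sorted by static-switchable hydration
#' count (descending), ties broken by `ddG_apo` ascending, then by the ion
#' interaction-energy change `ion_dE` ascending when present (criterion 3
#' as a second-order tie-break), and finally by `design_id`. Flagged
#' designs follow, same ordering, with their flag reasons.
#'
#' @param designs output of [apply_criteria].
#' @param config a [selection_config] (unused in ordering; kept for
#'   interface symmetry).
#' @return `designs` reordered, with `rank` and `flag_reason` columns.
#' @export
rank_designs <- function(designs, config = selection_config()) {
  if (!nrow(designs)) {
    designs$rank <- integer()
    designs$flag_reason <- character()
    return(designs)
  }
  flagged <- designs$c1_loss | designs$c2_fail
  ion <- if ("ion_dE" %in% names(designs)) designs$ion_dE else rep(0, nrow(designs))
  ion[is.na(ion)] <- 0
  ord <- order(flagged, -designs$n_static_switchable, designs$ddG_apo, ion,
               designs$design_id)
  out <- designs[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$flag_reason <- apply(out[, c("c1_loss", "c2_fail")], 1L, function(f) {
    paste(c(if (f[["c1_loss"]]) "c1_loss", if (f[["c2_fail"]]) "c2_fail"),
          collapse = ",")
  })
  rownames(out) <- NULL
  out
}

#' Read a design table
#'
#' TSV with columns matching the per-design record (`design_id`,
#' `dG_inactive`, `dG_active`, `ddG_apo`, `n_total_water_hb`,
#' `n_static_switchable`, optional `ion_dE`).
#' @param path TSV path.
#' @return data.frame.
#' @export
read_design_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Full selection pipeline
#'
#' [filter_unfolded], then [apply_criteria] and [rank_designs] on the
#' retained designs; discarded designs are appended with their reason.
#'
#' @param designs design table.
#' @param config a [selection_config].
#' @return data.frame: ranked retained designs followed by discarded ones
#'   (`rank` `NA`, `flag_reason` the discard reason).
#' @export
select_designs <- function(designs, config = selection_config()) {
  fl <- filter_unfolded(designs, config)
  ranked <- rank_designs(apply_criteria(fl$retained, config), config)
  if (nrow(fl$discarded)) {
    disc <- fl$discarded
    disc$c1_loss <- NA
    disc$c2_fail <- NA
    disc$class <- NA_character_
    disc$rank <- NA_integer_
    disc$flag_reason <- disc$reason
    disc$reason <- NULL
    common <- intersect(names(ranked), names(disc))
    ranked <- rbind(ranked[, common, drop = FALSE], disc[, common, drop = FALSE])
  }
  ranked
}
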