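# Bin-level aggregation and the four transfer free-energy estimators
# (contact, surface, area, scaled area), class pooling and reference
# correction. All energies are in kT units; positive values mean burial is
# favoured (hydrophobic).

#' Aggregate per-chain counts into bin-level counts
#'
#' Sums the sufficient statistics of one temperature bin. With coordination
#' number q, the solvent contacts of type a are \code{q * sum(alpha)} and the
#' total number of water contact points is \code{W = q * sum(alpha)} over all
#' residues.
#'
#' @param counts A \code{chain_counts} data.frame (all rows belong to the
#'   bin), as produced by \code{\link{chain_counts}} or
#'   \code{\link{read_counts_table}}.
#' @param q Coordination number; defaults to the attribute stored on
#'   \code{counts}, else 4.
#' @param max_asa Max-ASA scale used by the scaled-area estimator.
#' @return Object of class \code{bin_counts}: list with named per-type
#'   vectors \code{n}, \code{buried}, \code{alpha_sum}, scalars \code{q},
#'   \code{N}, \code{W}, \code{N_b}, \code{N_nb}, \code{chain_count},
#'   \code{temperature_mean} and the \code{max_asa} table.
#' @export
bin_counts <- function(counts, q = NULL, max_asa = default_max_asa()) {
  if (nrow(counts) == 0L) stop("EmptyBin: no chains", call. = FALSE)
  if (is.null(q)) q <- attr(counts, "q") %||% 4
  aa <- amino_acids()
  .bin_counts_from_sums(
    n = stats::setNames(colSums(counts[paste0("n_", aa)]), aa),
    buried = stats::setNames(colSums(counts[paste0("b_", aa)]), aa),
    alpha_sum = stats::setNames(colSums(counts[paste0("a_", aa)]), aa),
    q = q, max_asa = max_asa, chain_count = nrow(counts),
    temperature_mean = mean(counts$temperature)
  )
}

# shared constructor: also the fast path for resampling, where per-chain
# count rows are summed as a matrix without data.frame overhead
.bin_counts_from_sums <- function(n, buried, alpha_sum, q, max_asa,
                                  chain_count = NA_integer_,
                                  temperature_mean = NA_real_) {
  N <- sum(n)
  structure(
    list(n = n, buried = buried, alpha_sum = alpha_sum,
         q = q, N = N, W = q * sum(alpha_sum),
         N_b = sum(buried), N_nb = N - sum(buried),
         chain_count = chain_count,
         temperature_mean = temperature_mean,
         max_asa = max_asa),
    class = "bin_counts"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate chains directly into bin counts
#'
#' Convenience wrapper: \code{\link{chain_counts}} followed by
#' \code{\link{bin_counts}}.
#'
#' @inheritParams chain_counts
#' @inheritParams bin_counts
#' @export
aggregate_bin_counts <- function(chains, burial_cutoff = 0.07, q = 4,
                                 max_asa = default_max_asa()) {
  if (length(chains) == 0L) stop("EmptyBin: no chains", call. = FALSE)
  bin_counts(chain_counts(chains, burial_cutoff, q), q = q, max_asa = max_asa)
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("<bin counts: %d chains, %d residues, mean T = %.1f K>\n",
              x$chain_count, x$N, x$temperature_mean))
  invisible(x)
}

#' Contact-based solvent transfer energy
#'
#' Knowledge-based pair potential restricted to the residue-solvent column:
#' \code{-ln(c_aw / w_aw)} with observed solvent contacts
#' \code{c_aw = q * sum(alpha)} over residues of the pool and expected
#' contacts \code{w_aw = (n_a q) W / (q N + W)} under random mixing, where
#' \code{W} is the total number of water contact points. Pooling sums counts
#' over member types before evaluation.
#'
#' @param bc A \code{bin_counts} object.
#' @param entity Residue type or class name (see \code{\link{entity_types}}).
#' @return Energy in kT, or \code{NA} when the pool has no residues or no
#'   solvent contacts (missing cell, never +-Inf).
#' @export
contact_energy <- function(bc, entity) {
  types <- entity_types(entity)
  n_a <- sum(bc$n[types])
  c_aw <- bc$q * sum(bc$alpha_sum[types])
  if (n_a == 0 || c_aw <= 0) return(NA_real_)
  omega <- (n_a * bc$q) * bc$W / (bc$q * bc$N + bc$W)
  -log(c_aw / omega)
}

#' Surface (burial-propensity) transfer energy
#'
#' Partition-coefficient style propensity of a type to be buried relative to
#' the background: \code{ln[(N_ab / N_anb) / (N_b / N_nb)]}. Defined so that
#' swapping the buried and non-buried labels flips the sign exactly.
#'
#' @inheritParams contact_energy
#' @return Energy in kT, or \code{NA} when any of the four counts is zero.
#' @export
surface_energy <- function(bc, entity) {
  types <- entity_types(entity)
  N_ab <- sum(bc$buried[types])
  N_anb <- sum(bc$n[types]) - N_ab
  if (N_ab == 0 || N_anb == 0 || bc$N_b == 0 || bc$N_nb == 0)
    return(NA_real_)
  log((N_ab / N_anb) / (bc$N_b / bc$N_nb))
}

#' Area-based transfer energy
#'
#' Compares the exposed-area fraction of a type to the average residue:
#' \code{C_a = -ln[(N / n_a) * sum_{r in a}(alpha_r) / sum_all(alpha_r)]}.
#' The scaled variant multiplies by the maximum accessible area of the type
#' (for pools, the count-weighted mean over members), giving large residues
#' proportionally larger scores.
#'
#' @inheritParams contact_energy
#' @param scaled If \code{TRUE}, return \code{C_a * max(S_a)} (kT * A^2).
#' @return Energy, or \code{NA} when the pool has zero summed area.
#' @export
area_energy <- function(bc, entity, scaled = FALSE) {
  types <- entity_types(entity)
  n_a <- sum(bc$n[types])
  A_a <- sum(bc$alpha_sum[types])
  A_tot <- sum(bc$alpha_sum)
  if (n_a == 0 || A_a <= 0 || A_tot <= 0) return(NA_real_)
  C_a <- -log((bc$N / n_a) * A_a / A_tot)
  if (scaled)
    C_a <- C_a * stats::weighted.mean(bc$max_asa[types], bc$n[types])
  C_a
}

.methods <- c("contact", "surface", "area", "scaled_area")

#' Transfer energy by method name
#'
#' Dispatches to \code{\link{contact_energy}}, \code{\link{surface_energy}}
#' or \code{\link{area_energy}} and optionally subtracts the reference energy
#' of the pooled charged + polar residues of the same bin, making energies
#' comparable across temperature bins.
#'
#' @inheritParams contact_energy
#' @param method One of \code{"contact"}, \code{"surface"}, \code{"area"},
#'   \code{"scaled_area"}.
#' @param corrected Subtract the bin's reference energy?
#' @param reference_classes Classes pooled into the reference
#'   (default charged + polar).
#' @return Energy in kT (possibly \code{NA} for missing cells).
#' @export
transfer_energy <- function(bc, entity, method = .methods, corrected = FALSE,
                            reference_classes = c("charged", "polar")) {
  method <- match.arg(method)
  e <- switch(method,
    contact = contact_energy(bc, entity),
    surface = surface_energy(bc, entity),
    area = area_energy(bc, entity, scaled = FALSE),
    scaled_area = area_energy(bc, entity, scaled = TRUE)
  )
  if (corrected)
    e <- e - reference_energy(bc, method, reference_classes)
  e
}

#' Reference energy of a bin
#'
#' Raw transfer energy of the pooled reference residues (counts are summed
#' over the pool before evaluation, never averaged over per-type energies).
#'
#' @inheritParams transfer_energy
#' @export
reference_energy <- function(bc, method = .methods,
                             reference_classes = c("charged", "polar")) {
  method <- match.arg(method)
  types <- unlist(lapply(reference_classes, entity_types), use.names = FALSE)
  if (sum(bc$n[types]) == 0)
    stop("MissingReference: reference pool empty in bin", call. = FALSE)
  switch(method,
    contact = contact_energy(bc, types),
    surface = surface_energy(bc, types),
    area = area_energy(bc, types),
    scaled_area = area_energy(bc, types, scaled = TRUE)
  )
}

#' Long-format table of transfer energies
#'
#' One row per (bin, entity, method, corrected) combination; missing cells
#' (zero counts) carry \code{NA}. This is the package's PotentialTable.
#'
#' @param bins Named list of \code{bin_counts}, one per temperature bin.
#' @param entities Entities to evaluate (types and/or classes).
#' @param methods Subset of the four estimator names.
#' @param corrected Logical vector: which correction states to emit.
#' @inheritParams transfer_energy
#' @return data.frame with columns \code{bin}, \code{temperature_mean},
#'   \code{entity}, \code{method}, \code{corrected}, \code{dG_kT},
#'   \code{se_kT} (NA unless filled by \code{\link{add_split_errors}}),
#'   \code{n_residues} (pool size in the bin, the fit weight).
#' @export
energy_table <- function(bins, entities = c(amino_acids(), names(aa_classes())),
                         methods = .methods, corrected = c(FALSE, TRUE),
                         reference_classes = c("charged", "polar")) {
  stopifnot(length(bins) > 0L, !is.null(names(bins)))
  rows <- list()
  for (b in names(bins)) {
    bc <- bins[[b]]
    for (ent in entities) for (m in methods) for (corr in corrected) {
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, temperature_mean = bc$temperature_mean,
        entity = ent, method = m, corrected = corr,
        dG_kT = transfer_energy(bc, ent, m, corrected = corr,
                                reference_classes = reference_classes),
        se_kT = NA_real_,
        n_residues = sum(bc$n[entity_types(ent)]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Reference-correct an energy table
#'
#' Subtracts, per bin and method, the pooled reference energy recomputed from
#' the bin counts. Uncorrected rows are returned with \code{corrected = TRUE}
#' and shifted \code{dG_kT}; within-bin differences between entities are
#' preserved (the correction is a constant shift per bin and method).
#'
#' @param table Energy table with \code{corrected = FALSE} rows.
#' @param bins The named list of \code{bin_counts} the table came from.
#' @inheritParams transfer_energy
#' @export
reference_correct <- function(table, bins,
                              reference_classes = c("charged", "polar")) {
  tab <- table[!table$corrected, , drop = FALSE]
  for (i in seq_len(nrow(tab))) {
    ref <- reference_energy(bins[[tab$bin[i]]], tab$method[i],
                            reference_classes)
    tab$dG_kT[i] <- tab$dG_kT[i] - ref
  }
  tab$corrected <- TRUE
  tab
}
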