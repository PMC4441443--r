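# Temperature binning, split-sample standard errors, permutation
# significance of the low-vs-room free-energy difference, and weighted
# parabola fits of energy against temperature.

#' The five temperature bins
#'
#' Inclusive integer-kelvin ranges chosen symmetrically around the room
#' temperature peak of the NMR record: 265-290, 291-296, 297-299, 300-305
#' and 306-340 K.
#'
#' @return data.frame with columns \code{bin}, \code{low}, \code{high}.
#' @export
temperature_bins <- function() {
  data.frame(
    bin = c("265-290", "291-296", "297-299", "300-305", "306-340"),
    low = c(265L, 291L, 297L, 300L, 306L),
    high = c(290L, 296L, 299L, 305L, 340L),
    stringsAsFactors = FALSE
  )
}

#' Assign temperatures to bins
#'
#' Temperatures are rounded to the nearest integer kelvin before the
#' inclusive-range lookup (bin bounds are integers; reported temperatures may
#' be fractional). Values outside 265-340 K are excluded (\code{NA}).
#'
#' @param temperature Numeric vector, kelvin.
#' @param bins Bin definition as from \code{\link{temperature_bins}}.
#' @return Character vector of bin ids, \code{NA} where excluded.
#' @export
assign_bin <- function(temperature, bins = temperature_bins()) {
  t0 <- round(temperature)
  out <- rep(NA_character_, length(t0))
  for (i in seq_len(nrow(bins))) {
    hit <- !is.na(t0) & t0 >= bins$low[i] & t0 <= bins$high[i]
    out[hit] <- bins$bin[i]
  }
  out
}

#' Split per-chain counts by temperature bin
#'
#' @param counts A \code{chain_counts} data.frame.
#' @param bins Bin definition.
#' @param max_asa Max-ASA scale forwarded to \code{\link{bin_counts}}.
#' @return List with \code{by_bin} (named list of \code{chain_counts}
#'   subsets, empty bins omitted), \code{bin_counts} (named list of
#'   aggregated \code{bin_counts}) and \code{excluded} (rows outside all
#'   bins).
#' @export
split_by_bin <- function(counts, bins = temperature_bins(),
                         max_asa = default_max_asa()) {
  id <- assign_bin(counts$temperature, bins)
  by_bin <- lapply(stats::setNames(bins$bin, bins$bin),
                   function(b) counts[!is.na(id) & id == b, , drop = FALSE])
  by_bin <- Filter(function(x) nrow(x) > 0L, by_bin)
  list(
    by_bin = by_bin,
    bin_counts = lapply(by_bin, bin_counts, q = attr(counts, "q") %||% 4,
                        max_asa = max_asa),
    excluded = counts[is.na(id), , drop = FALSE]
  )
}

#' Free-energy difference between two bins
#'
#' \code{ddG = dG(room bin) - dG(low bin)}: positive when the core-to-surface
#' transfer cost is larger at room temperature, i.e. when hydrophobicity
#' weakens on cooling.
#'
#' @param table An energy table from \code{\link{energy_table}}.
#' @param entity,method,corrected Cell selectors.
#' @param bin_low,bin_room The two bins compared (defaults: lowest bin and
#'   room temperature).
#' @return Energy difference in kT.
#' @export
delta_delta_g <- function(table, entity, method, corrected = FALSE,
                          bin_low = "265-290", bin_room = "297-299") {
  cell <- function(b) {
    i <- table$bin == b & table$entity == entity & table$method == method &
      table$corrected == corrected
    if (sum(i) != 1L || is.na(table$dG_kT[i]))
      stop("MissingCell: ", entity, "/", method, " in bin ", b, call. = FALSE)
    table$dG_kT[i]
  }
  cell(bin_room) - cell(bin_low)
}

#' ddG recomputed from per-chain counts
#'
#' Aggregates the two chain sets and evaluates the difference directly; this
#' is the statistic permuted by \code{\link{resample_pvalue}}. When
#' \code{corrected}, the reference correction is recomputed for each chain
#' set (and hence inside every resample).
#'
#' @param rows_low,rows_room \code{chain_counts} rows of the two bins.
#' @inheritParams transfer_energy
#' @param max_asa Max-ASA scale.
#' @return Energy difference in kT (\code{NA} if either cell is missing).
#' @export
ddg_counts <- function(rows_low, rows_room, entity, method,
                       corrected = FALSE,
                       reference_classes = c("charged", "polar"),
                       max_asa = default_max_asa()) {
  e <- function(rows) {
    bc <- bin_counts(rows, max_asa = max_asa)
    transfer_energy(bc, entity, method, corrected = corrected,
                    reference_classes = reference_classes)
  }
  e(rows_room) - e(rows_low)
}

#' Split-sample standard error
#'
#' Splits the chains of one bin at random into \code{k} parts of equal size
#' (remainders spread round-robin), recomputes the estimator on each part and
#' reports \code{SE = sd(parts) / sqrt(k)}. Two SEs on each side of the
#' full-sample estimate give an approximate 95 percent confidence interval.
#'
#' @param counts \code{chain_counts} rows of the bin.
#' @param estimator Function taking a \code{chain_counts} subset and
#'   returning a numeric scalar (or named vector) estimate.
#' @param k Number of parts (default 5).
#' @param seed Optional integer seed making the random partition
#'   reproducible.
#' @return List with \code{se}, \code{estimates} (k x p matrix) and
#'   \code{k}.
#' @export
split_standard_error <- function(counts, estimator, k = 5, seed = NULL) {
  n <- nrow(counts)
  if (n < k) stop("TooFewChains: ", n, " chains for k = ", k, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  part <- rep_len(seq_len(k), n)[sample.int(n)]
  est <- lapply(seq_len(k), function(p)
    estimator(counts[part == p, , drop = FALSE]))
  est <- do.call(rbind, lapply(est, rbind))
  se <- apply(est, 2L, stats::sd) / sqrt(k)
  list(se = unname(se)[if (ncol(est) == 1L) 1L else TRUE],
       estimates = est, k = k)
}

#' Split-sample standard error of a two-bin difference
#'
#' Partitions each bin independently into \code{k} parts, pairs them, and
#' takes the spread of the k paired ddG estimates.
#'
#' @inheritParams ddg_counts
#' @inheritParams split_standard_error
#' @export
split_se_ddg <- function(rows_low, rows_room, entity, method,
                         corrected = FALSE, k = 5, seed = NULL,
                         reference_classes = c("charged", "polar"),
                         max_asa = default_max_asa()) {
  if (nrow(rows_low) < k || nrow(rows_room) < k)
    stop("TooFewChains for k = ", k, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p1 <- rep_len(seq_len(k), nrow(rows_low))[sample.int(nrow(rows_low))]
  p2 <- rep_len(seq_len(k), nrow(rows_room))[sample.int(nrow(rows_room))]
  est <- vapply(seq_len(k), function(p) {
    ddg_counts(rows_low[p1 == p, , drop = FALSE],
               rows_room[p2 == p, , drop = FALSE],
               entity, method, corrected, reference_classes, max_asa)
  }, 0)
  list(se = stats::sd(est) / sqrt(k), estimates = est, k = k)
}

#' Fill split-sample standard errors into an energy table
#'
#' @param table Energy table (\code{\link{energy_table}}).
#' @param by_bin Named list of per-bin \code{chain_counts}
#'   (\code{\link{split_by_bin}}\code{$by_bin}).
#' @inheritParams split_standard_error
#' @inheritParams ddg_counts
#' @export
add_split_errors <- function(table, by_bin, k = 5, seed = NULL,
                             reference_classes = c("charged", "polar"),
                             max_asa = default_max_asa()) {
  if (!is.null(seed)) set.seed(seed)
  for (b in unique(table$bin)) {
    rows <- by_bin[[b]]
    if (is.null(rows) || nrow(rows) < k) next
    sel <- which(table$bin == b)
    est <- function(sub) {
      bc <- bin_counts(sub, max_asa = max_asa)
      vapply(sel, function(i)
        transfer_energy(bc, table$entity[i], table$method[i],
                        corrected = table$corrected[i],
                        reference_classes = reference_classes), 0)
    }
    res <- split_standard_error(rows, est, k = k)
    table$se_kT[sel] <- res$se
  }
  table
}

#' Permutation p-value for the temperature dependence
#'
#' Pools the chains of the two bins, shuffles their temperature labels
#' (preserving the two bin sizes), recomputes the ddG statistic for each of
#' \code{n} resamples, and reports the fraction of resampled differences at
#' least as large in absolute size as the observed one (ties and
#' non-finite resamples count as exceedances).
#'
#' @inheritParams ddg_counts
#' @param n Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return Object of class \code{significance_result}: list with
#'   \code{observed} (kT), \code{p_value}, \code{n_resamples}, \code{seed}
#'   and the vector of \code{resamples}.
#' @export
resample_pvalue <- function(rows_low, rows_room, entity, method,
                            corrected = FALSE, n = 1000, seed = NULL,
                            reference_classes = c("charged", "polar"),
                            max_asa = default_max_asa()) {
  if (nrow(rows_low) == 0L || nrow(rows_room) == 0L)
    stop("EmptyBin: both bins need chains", call. = FALSE)
  obs <- ddg_counts(rows_low, rows_room, entity, method, corrected,
                    reference_classes, max_asa)
  q <- attr(rows_low, "q") %||% 4
  aa <- amino_acids()
  cols <- c(paste0("n_", aa), paste0("b_", aa), paste0("a_", aa))
  M <- as.matrix(rbind(as.data.frame(rows_low)[cols],
                       as.data.frame(rows_room)[cols]))
  tot <- colSums(M)
  n_low <- nrow(rows_low)
  N <- nrow(M)
  bc_of <- function(s)
    .bin_counts_from_sums(
      n = stats::setNames(s[1:20], aa),
      buried = stats::setNames(s[21:40], aa),
      alpha_sum = stats::setNames(s[41:60], aa),
      q = q, max_asa = max_asa)
  stat_of <- function(s_low) {
    e <- function(bc) transfer_energy(bc, entity, method,
                                      corrected = corrected,
                                      reference_classes = reference_classes)
    e(bc_of(tot - s_low)) - e(bc_of(s_low))
  }
  if (!is.null(seed)) set.seed(seed)
  stats_star <- vapply(seq_len(n), function(b) {
    idx <- sample.int(N, n_low)
    stat_of(colSums(M[idx, , drop = FALSE]))
  }, 0)
  exceed <- !is.finite(stats_star) | abs(stats_star) >= abs(obs)
  structure(
    list(observed = obs, p_value = mean(exceed), n_resamples = n,
         seed = seed, resamples = stats_star),
    class = "significance_result"
  )
}

#' @export
print.significance_result <- function(x, ...) {
  p <- if (x$p_value < 1 / x$n_resamples) {
    sprintf("< %g", 1 / x$n_resamples)
  } else {
    format(x$p_value)
  }
  cat(sprintf("ddG = %.4f kT, p %s (%d resamples)\n",
              x$observed, p, x$n_resamples))
  invisible(x)
}

#' Weighted least-squares parabola fit
#'
#' Fits \code{dG(T) = a2 T^2 + a1 T + a0} by minimising
#' \code{S = sum(w_i r_i^2)}, with the residue count of the entity per bin as
#' the natural weight and the bin's mean chain temperature as abscissa.
#' Solved via QR on the weighted design matrix (equivalent to the normal
#' equations but better conditioned).
#'
#' @param temperature Bin mean temperatures (kelvin).
#' @param energy Energies (kT); \code{NA} cells are dropped.
#' @param weights Non-negative weights (default: equal, i.e. ordinary least
#'   squares).
#' @return Object of class \code{parabola_fit}: coefficients
#'   \code{c(a0, a1, a2)}, \code{vertex} \code{= -a1 / (2 a2)} (kelvin),
#'   \code{is_max} (\code{TRUE} iff \code{a2 < 0}, i.e. the vertex is the
#'   maximum of the curve — only then is it interpreted as the temperature
#'   of strongest hydrophobicity), \code{fitted}, \code{residuals},
#'   \code{weights} and the minimised \code{S}.
#' @export
fit_parabola <- function(temperature, energy, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(energy))
  stopifnot(length(temperature) == length(energy),
            length(weights) == length(energy))
  ok <- is.finite(temperature) & is.finite(energy) & is.finite(weights) &
    weights > 0
  temperature <- temperature[ok]; energy <- energy[ok]; weights <- weights[ok]
  if (length(energy) < 3L || length(unique(temperature)) < 3L)
    stop("DegenerateFit: need >= 3 points with distinct temperatures",
         call. = FALSE)
  X <- cbind(1, temperature, temperature^2)
  sw <- sqrt(weights)
  fit <- qr.solve(X * sw, energy * sw)
  coef <- stats::setNames(as.numeric(fit), c("a0", "a1", "a2"))
  fitted <- as.numeric(X %*% coef)
  r <- energy - fitted
  structure(
    list(coefficients = coef,
         vertex = if (coef["a2"] != 0) unname(-coef["a1"] / (2 * coef["a2"]))
                  else NA_real_,
         is_max = unname(coef["a2"] < 0),
         fitted = fitted, residuals = r, weights = weights,
         temperature = temperature, S = sum(weights * r^2)),
    class = "parabola_fit"
  )
}

#' @export
print.parabola_fit <- function(x, ...) {
  cat(sprintf("dG(T) = %.3g T^2 + %.3g T + %.3g", x$coefficients["a2"],
              x$coefficients["a1"], x$coefficients["a0"]))
  if (isTRUE(x$is_max)) cat(sprintf("  (maximum at %.1f K)", x$vertex))
  cat(sprintf("\nweighted residual sum S = %.4g on %d points\n",
              x$S, length(x$residuals)))
  invisible(x)
}
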