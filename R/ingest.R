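# Parsing of PDB headers / DSSP accessibility output, chain construction,
# filtering, and the per-chain counts table (S1-style TSV).

#' Parse the acquisition temperature from a PDB-format header
#'
#' NMR entries record the experiment temperature in the mandatory
#' acquisition-data block (\code{REMARK 210  TEMPERATURE (K) : ...}).
#' Entries resolved in several data-collection sessions may carry several
#' values, either separated by semicolons on one line or on repeated lines.
#' Rather than raising an R error, the outcome is returned as a typed status
#' so that filtering can tally rejection reasons.
#'
#' @param header_text Character vector of header lines (or a single string
#'   with embedded newlines).
#' @param implausible_below Temperatures at or below this value (kelvin) are
#'   rejected; the default 150 K separates genuine cryo/NMR temperatures from
#'   the artefact of temperatures entered in celsius, which cluster just
#'   above absolute zero.
#' @return An object of class \code{acq_temperature}: a list with
#'   \code{temperature} (kelvin, or \code{NA}), \code{status} (one of
#'   \code{"ok"}, \code{"missing"}, \code{"multiple"}, \code{"implausible"})
#'   and \code{values} (all numbers seen).
#' @export
parse_pdb_temperature <- function(header_text, implausible_below = 150) {
  lines <- unlist(strsplit(header_text, "\n", fixed = TRUE), use.names = FALSE)
  tlines <- grep("^REMARK\\s+210\\s+TEMPERATURE", lines, value = TRUE)
  vals <- numeric(0)
  for (ln in tlines) {
    rhs <- sub("^[^:]*:", "", ln)
    toks <- trimws(unlist(strsplit(rhs, "[;,]")))
    toks <- toks[nzchar(toks) & toupper(toks) != "NULL"]
    vals <- c(vals, suppressWarnings(as.numeric(sub("\\s*K$", "", toks))))
  }
  vals <- vals[is.finite(vals)]
  status <- if (length(vals) == 0L) {
    "missing"
  } else if (length(unique(vals)) > 1L) {
    "multiple"
  } else if (vals[1L] <= implausible_below) {
    "implausible"
  } else {
    "ok"
  }
  structure(
    list(temperature = if (status == "ok") vals[1L] else NA_real_,
         status = status, values = vals),
    class = "acq_temperature"
  )
}

#' Parse a DSSP output file
#'
#' Reads the per-residue records of a classic (fixed-width) DSSP file and
#' extracts chain, residue number, residue type and accessible surface area
#' (the ACC column). Chain-break markers (\code{!}) are skipped; lower-case
#' letters (disulfide-bridged cysteines) map to CYS; unrecognised codes get
#' \code{NA} for the type and are dropped later by
#' \code{\link{build_chain_record}}.
#'
#' @param path Path to a DSSP file.
#' @return \code{data.frame} with columns \code{chain}, \code{resnum},
#'   \code{aa} (three-letter, or NA) and \code{acc} (squared Angstrom).
#' @export
parse_dssp <- function(path) {
  if (!file.exists(path)) stop("no such DSSP file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L)
    stop("not a DSSP file (no '  #  RESIDUE' header): ", path, call. = FALSE)
  body <- lines[seq.int(hdr[1L] + 1L, length(lines))]
  body <- body[nchar(body) >= 38L]
  aa1 <- substr(body, 14L, 14L)
  keep <- aa1 != "!"
  body <- body[keep]
  aa1 <- aa1[keep]
  aa1[aa1 %in% letters] <- "C"  # SS-bonded CYS are labelled a-z
  data.frame(
    chain = trimws(substr(body, 12L, 12L)),
    resnum = suppressWarnings(as.integer(trimws(substr(body, 6L, 10L)))),
    aa = unname(.AA1TO3[aa1]),
    acc = as.numeric(trimws(substr(body, 35L, 38L))),
    stringsAsFactors = FALSE
  )
}

#' Construct a chain record from per-model accessibilities
#'
#' NMR depositions contain an ensemble of models; the accessible area of each
#' residue is averaged over models before conversion to an exposure fraction
#' alpha = min(1, mean area / max area of the type). Areas above the
#' tabulated maximum (extended conformations) are clamped to alpha = 1.
#'
#' @param structure_id,chain_id Identifiers (e.g. PDB id and chain letter).
#' @param temperature Acquisition temperature in kelvin.
#' @param models List of data.frames with columns \code{aa} and \code{acc},
#'   one per model, all with the same residue sequence.
#' @param max_asa Named vector of per-type maximum accessible areas.
#' @return A \code{chain_record}: list with \code{structure_id},
#'   \code{chain_id}, \code{temperature} and a \code{residues} data.frame
#'   (\code{aa}, \code{mean_area}, \code{exposure}, plus a
#'   \code{per_model_area} matrix attribute with one column per model).
#' @export
build_chain_record <- function(structure_id, chain_id, temperature, models,
                               max_asa = default_max_asa()) {
  stopifnot(is.list(models), length(models) >= 1L)
  ref <- models[[1L]]
  for (m in models[-1L]) {
    if (nrow(m) != nrow(ref) || !identical(m$aa, ref$aa))
      stop("ModelMismatch: models disagree in residue count or types for ",
           structure_id, "_", chain_id, call. = FALSE)
  }
  areas <- vapply(models, function(m) as.numeric(m$acc), numeric(nrow(ref)))
  areas <- matrix(areas, nrow = nrow(ref))
  aa <- ref$aa
  known <- !is.na(aa) & aa %in% amino_acids()
  if (any(!known)) {
    warning(sum(!known), " nonstandard residue(s) dropped in ",
            structure_id, "_", chain_id, call. = FALSE)
    aa <- aa[known]
    areas <- areas[known, , drop = FALSE]
  }
  mean_area <- rowMeans(areas)
  residues <- data.frame(
    aa = aa,
    mean_area = mean_area,
    exposure = pmin(1, mean_area / unname(max_asa[aa])),
    stringsAsFactors = FALSE
  )
  attr(residues, "per_model_area") <- areas
  chain_record(structure_id, chain_id, temperature, residues)
}

#' Create and validate a chain record
#'
#' @param structure_id,chain_id Identifiers.
#' @param temperature Kelvin; must be a single finite value.
#' @param residues data.frame with columns \code{aa}, \code{mean_area} and
#'   \code{exposure} (in [0, 1]); must be non-empty.
#' @return Object of class \code{chain_record}.
#' @export
chain_record <- function(structure_id, chain_id, temperature, residues) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature))
    stop("temperature must be a single finite value", call. = FALSE)
  if (nrow(residues) == 0L)
    stop("chain has no standard residues: ", structure_id, "_", chain_id,
         call. = FALSE)
  if (any(residues$exposure < 0 | residues$exposure > 1))
    stop("exposure fractions outside [0, 1]", call. = FALSE)
  structure(
    list(structure_id = as.character(structure_id),
         chain_id = as.character(chain_id),
         temperature = temperature,
         residues = residues),
    class = "chain_record"
  )
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain %s_%s: %d residues, T = %.1f K>\n",
              x$structure_id, x$chain_id, nrow(x$residues), x$temperature))
  invisible(x)
}

#' A rejected chain candidate
#'
#' Used by \code{\link{apply_filters}} to carry typed rejection reasons
#' (e.g. a failed temperature parse or an accessibility-parse failure)
#' through the filter accounting.
#'
#' @param structure_id,chain_id Identifiers.
#' @param reason One of \code{"temperature"}, \code{"parse"}.
#' @return Object of class \code{chain_rejection}.
#' @export
chain_rejection <- function(structure_id, chain_id,
                            reason = c("temperature", "parse")) {
  reason <- match.arg(reason)
  structure(list(structure_id = as.character(structure_id),
                 chain_id = as.character(chain_id), reason = reason),
            class = "chain_rejection")
}

#' Apply the study filters to a set of chain candidates
#'
#' Retains candidates that (1) parsed into a valid \code{chain_record} with a
#' single plausible temperature, and (2) appear in the redundancy-reduced
#' select-25 chain list. Filtering is total: every input chain is either
#' retained or tallied under exactly one exclusion reason
#' (\code{temperature}, \code{parse}, \code{redundancy}).
#'
#' @param candidates List whose elements are \code{chain_record} or
#'   \code{chain_rejection} objects.
#' @param select25_ids Character vector of retained chain identifiers in
#'   \code{"1ABC_A"} form (case-insensitive).
#' @return List with \code{chains} (retained \code{chain_record}s) and
#'   \code{tally} (named integer vector: retained + per-reason exclusions).
#' @export
apply_filters <- function(candidates, select25_ids) {
  select25_ids <- toupper(trimws(select25_ids))
  tally <- c(retained = 0L, temperature = 0L, parse = 0L, redundancy = 0L)
  chains <- list()
  for (cand in candidates) {
    if (inherits(cand, "chain_rejection")) {
      tally[cand$reason] <- tally[cand$reason] + 1L
      next
    }
    stopifnot(inherits(cand, "chain_record"))
    id <- toupper(paste(cand$structure_id, cand$chain_id, sep = "_"))
    if (!(id %in% select25_ids)) {
      tally["redundancy"] <- tally["redundancy"] + 1L
      next
    }
    tally["retained"] <- tally["retained"] + 1L
    chains[[length(chains) + 1L]] <- cand
  }
  list(chains = chains, tally = tally)
}

#' Read a select-25 style chain list
#'
#' One chain identifier (\code{1ABC_A}) per line; blank lines and lines
#' starting with \code{#} are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of upper-cased identifiers.
#' @export
read_select25 <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  toupper(x[nzchar(x) & !startsWith(x, "#")])
}

# column names of the per-chain counts schema
.counts_columns <- function() {
  aa <- amino_acids()
  c("structure_id", "chain_id", "temperature",
    paste0("n_", aa), paste0("b_", aa), paste0("a_", aa))
}

#' Per-chain counts
#'
#' Reduces chains to the sufficient statistics of all four estimators: for
#' each residue type, the residue count \code{n_*}, the buried count
#' \code{b_*} (exposure strictly below the burial cutoff) and the summed
#' exposure fraction \code{a_*}. Solvent contacts are \code{q * a_*}, so they
#' need not be stored separately.
#'
#' @param chains List of \code{chain_record}s.
#' @param burial_cutoff Relative-accessibility threshold below which a
#'   residue counts as buried (strict \code{<}); default 0.07.
#' @param q Coordination number (contact slots per residue); default 4.
#' @return Object of class \code{chain_counts}: a data.frame, one row per
#'   chain, with the schema of \code{.counts_columns()}; \code{burial_cutoff}
#'   and \code{q} are carried as attributes.
#' @export
chain_counts <- function(chains, burial_cutoff = 0.07, q = 4) {
  stopifnot(burial_cutoff > 0, burial_cutoff < 1, q > 0)
  aa <- amino_acids()
  n <- length(chains)
  mat <- matrix(0, nrow = n, ncol = 60L,
                dimnames = list(NULL, .counts_columns()[-(1:3)]))
  sid <- character(n); cid <- character(n); temp <- numeric(n)
  for (i in seq_len(n)) {
    ch <- chains[[i]]
    stopifnot(inherits(ch, "chain_record"))
    idx <- match(ch$residues$aa, aa)
    expo <- ch$residues$exposure
    mat[i, 1:20] <- tabulate(idx, 20L)
    mat[i, 21:40] <- tabulate(idx[expo < burial_cutoff], 20L)
    mat[i, 41:60] <- vapply(seq_len(20L),
                            function(k) sum(expo[idx == k]), 0)
    sid[i] <- ch$structure_id; cid[i] <- ch$chain_id
    temp[i] <- ch$temperature
  }
  out <- data.frame(structure_id = sid, chain_id = cid, temperature = temp,
                    mat, stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, burial_cutoff = burial_cutoff, q = q,
            class = c("chain_counts", "data.frame"))
}

#' @export
`[.chain_counts` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "burial_cutoff") <- attr(x, "burial_cutoff")
    attr(out, "q") <- attr(x, "q")
    class(out) <- class(x)
  }
  out
}

#' Write / read the per-chain counts table
#'
#' Tab-separated, one row per chain, header row naming columns; numeric
#' fields are written with 17 significant digits so a round trip is exact.
#'
#' @param counts A \code{chain_counts} data.frame.
#' @param path Output (or input) TSV path.
#' @return \code{write_counts_table} returns \code{path} invisibly;
#'   \code{read_counts_table} returns a \code{chain_counts} data.frame.
#' @export
write_counts_table <- function(counts, path) {
  df <- as.data.frame(counts)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("no such counts table: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty counts table: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1L]])
  bad <- which(lengths(fields) != ncol)
  if (length(bad) > 0L)
    stop("MalformedRow: ", path, " line ", bad[1L], " has ",
         lengths(fields)[bad[1L]], " fields, expected ", ncol, call. = FALSE)
  header <- fields[[1L]]
  required <- .counts_columns()
  missing <- setdiff(required, header)
  if (length(missing) > 0L)
    stop("counts table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  body <- fields[-1L]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(character(0), ncol = ncol,
                               dimnames = list(NULL, header)),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
    names(df) <- header
  }
  df <- df[required]  # schema-driven: extra columns are ignored
  for (col in required[-(1:2)]) df[[col]] <- as.numeric(df[[col]])
  structure(df, class = c("chain_counts", "data.frame"))
}
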