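#' Validate a species table
#'
#' A species table is a data frame with one row per species and columns
#' `species_id`, `genus`, `body_mass_g` (body mass M, grams),
#' `mass_specific_rate_Wg` (mass-specific metabolic rate B_c, W/g), and
#' optionally `metabolic_rate_W` (whole-organism rate B, watts) and
#' `genome_year` (year the genome sequence was first completed).
#'
#' Checks: positive masses and rates, unique species ids, and — when the
#' whole-organism rate is present — consistency B_c = B / M to a relative
#' tolerance of 1e-9.
#'
#' @param x data frame to validate.
#' @return `x` invisibly, if valid; otherwise an error is thrown.
#' @export
validate_species_table <- function(x) {
  required <- c("species_id", "genus", "body_mass_g", "mass_specific_rate_Wg")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("species table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(x$species_id)) {
    dup <- unique(x$species_id[duplicated(x$species_id)])
    stop("duplicate species_id: ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(x$body_mass_g)) || any(x$body_mass_g <= 0)) {
    stop("body_mass_g must be positive and finite for every species")
  }
  if (any(!is.finite(x$mass_specific_rate_Wg)) || any(x$mass_specific_rate_Wg <= 0)) {
    stop("mass_specific_rate_Wg must be positive and finite for every species")
  }
  if ("metabolic_rate_W" %in% names(x)) {
    ok <- is.na(x$metabolic_rate_W) |
      abs(x$mass_specific_rate_Wg - x$metabolic_rate_W / x$body_mass_g) /
        x$mass_specific_rate_Wg < 1e-9
    if (!all(ok)) {
      stop("mass_specific_rate_Wg inconsistent with metabolic_rate_W / body_mass_g for: ",
           paste(x$species_id[!ok], collapse = ", "))
    }
  }
  invisible(x)
}

#' Read / write a species table (TSV)
#'
#' @param path file path of a tab-separated table with a header row.
#' @return `read_species_table`: a validated species table data frame.
#' @export
read_species_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_species_table(x)
}

#' @rdname read_species_table
#' @param x species table.
#' @export
write_species_table <- function(x, path) {
  validate_species_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep one representative species per genus
#'
#' When several congeneric species carry a sequenced genome, keeps a single
#' representative per genus, chosen by genome completion year. The default
#' keeps the species whose genome was completed earliest (typically the most
#' mature annotation); ties are broken lexicographically by `species_id`.
#'
#' @param table species table with `genus` and `genome_year` populated.
#' @param prefer `"earliest"` (default) or `"latest"` completion year.
#' @return species table with exactly one row per genus, in the original
#'   row order of the retained species.
#' @export
select_representatives <- function(table, prefer = c("earliest", "latest")) {
  prefer <- match.arg(prefer)
  validate_species_table(table)
  if (is.null(table$genus)) stop("genus column required")
  multi <- names(which(table(table$genus) > 1L))
  if (length(multi) > 0L) {
    bad <- vapply(multi, function(g) {
      any(is.na(table$genome_year[table$genus == g])) ||
        is.null(table$genome_year)
    }, logical(1L))
    if (is.null(table$genome_year) || any(bad)) {
      stop("genome_year missing for multi-species genus: ",
           paste(multi[if (is.null(table$genome_year)) TRUE else bad],
                 collapse = ", "))
    }
  }
  keep <- unlist(lapply(split(seq_len(nrow(table)), table$genus), function(idx) {
    if (length(idx) == 1L) return(idx)
    yr <- table$genome_year[idx]
    if (prefer == "latest") yr <- -yr
    # min year, then species_id tie-break
    best <- idx[yr == min(yr)]
    best[order(table$species_id[best])][1L]
  }), use.names = FALSE)
  table[sort(keep), , drop = FALSE]
}
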