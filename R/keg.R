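#' Count genes per third-level category in a KEGG BRITE flat file
#'
#' KEGG BRITE `.keg` flat files encode the functional hierarchy with line
#' prefixes `A`/`B`/`C`/`D`: `A` and `B` lines are first- and second-level
#' headings, `C` lines are third-level functional categories, and `D` lines
#' beneath a `C` line are individual gene entries. This parser returns, for
#' every `C`-level category in the file, the number of distinct genes listed
#' under it.
#'
#' Gene identity is the first whitespace-delimited token of the `D` line
#' content; a gene listed twice under one category is counted once. HTML
#' markup (e.g. `<b>...</b>`) in headings and category labels is stripped.
#' Categories with no `D` lines get count 0. A `D` line with no open `C`
#' category (before any `C`, or directly after an `A`/`B` heading) is a
#' format error.
#'
#' @param keg_text a single string or character vector of lines in BRITE
#'   flat format.
#' @return named integer vector: distinct gene count per category label.
#' @export
count_genes_per_category <- function(keg_text) {
  lines <- if (length(keg_text) == 1L && grepl("\n", keg_text, fixed = TRUE)) {
    strsplit(keg_text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(keg_text)
  }
  strip_html <- function(s) trimws(gsub("<[^>]+>", "", s))
  counts <- integer(0L)
  genes <- list()       # per-category distinct gene tokens
  current <- NA_character_
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    prefix <- substr(line, 1L, 1L)
    body <- strip_html(substr(line, 2L, nchar(line)))
    if (prefix %in% c("A", "B")) {
      current <- NA_character_          # D lines are counted only under an open C
    } else if (prefix == "C") {
      current <- body
      if (is.null(genes[[current]])) {
        genes[[current]] <- character(0L)
        counts[current] <- 0L
      }
    } else if (prefix == "D") {
      if (is.na(current)) {
        stop("format error at line ", i, ": gene (D) entry with no open C-level category")
      }
      token <- strsplit(body, "[[:space:]]+")[[1L]][1L]
      if (!is.na(token) && nzchar(token) && !(token %in% genes[[current]])) {
        genes[[current]] <- c(genes[[current]], token)
        counts[current] <- counts[current] + 1L
      }
    }
    # other prefixes (#, %, !, +) are BRITE metadata; ignored
  }
  counts
}

#' Build a species-by-category count matrix from BRITE flat files
#'
#' Applies [count_genes_per_category()] to one `.keg` text per species and
#' assembles the per-species counts into a single NOGF matrix over the union
#' of categories (absent categories filled with 0).
#'
#' @param keg_texts named list (names = species ids) of `.keg` file contents.
#' @return integer matrix, species as rows, categories as columns.
#' @export
build_function_matrix <- function(keg_texts) {
  if (is.null(names(keg_texts)) || any(!nzchar(names(keg_texts)))) {
    stop("keg_texts must be a named list keyed by species id")
  }
  per_sp <- lapply(keg_texts, count_genes_per_category)
  cats <- unique(unlist(lapply(per_sp, names)))
  m <- matrix(0L, nrow = length(per_sp), ncol = length(cats),
              dimnames = list(names(keg_texts), cats))
  for (sp in names(per_sp)) {
    v <- per_sp[[sp]]
    m[sp, names(v)] <- v
  }
  validate_function_matrix(m)
}
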