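# PT -> primary SOC mapping through a pluggable dictionary file.
#
# MedDRA itself is licensed and is not distributed here; the package ships a
# small dictionary covering the terms used by the synthetic generator and
# the bundled validation tables. Real analyses plug in their own full
# dictionary in the same two-column format.

#' Load a PT-to-SOC dictionary
#'
#' Reads a tab-separated dictionary file mapping each MedDRA preferred term
#' (PT) to exactly one primary system organ class (SOC). The format is
#' `PT<TAB>SOC` with optional `#` comment lines and an optional
#' `version: <label>` header line. MedDRA is multi-axial (a PT may belong to
#' several SOCs); this package resolves that by requiring a primary-SOC-only
#' dictionary, so a PT mapped to two different SOCs is an error, while
#' exactly duplicated rows are collapsed.
#'
#' @param path path to the dictionary file.
#' @return an object of class `meddra_dictionary` with elements `version`,
#'   `entries` (data.frame with columns `pt`, `soc`) and `soc_list`.
#' @export
read_meddra <- function(path) {
  if (!file.exists(path)) stop("dictionary file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  version <- NA_character_
  vline <- grepl("^\\s*version:", lines)
  if (any(vline)) {
    version <- trimws(sub("^\\s*version:", "", lines[which(vline)[1]]))
  }
  lines <- lines[!vline & !grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty dictionary: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop("dictionary line without a <TAB> separator: ",
         lines[which(nf < 2)[1]])
  }
  entries <- data.frame(
    pt = trimws(vapply(parts, `[[`, "", 1L)),
    soc = trimws(vapply(parts, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  entries <- unique(entries)
  key <- tolower(entries$pt)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop("PT mapped to more than one SOC: ",
         paste(entries$pt[match(dup, key)], collapse = ", "))
  }
  structure(
    list(version = version, entries = entries,
         soc_list = sort(unique(entries$soc))),
    class = "meddra_dictionary"
  )
}

#' Write a PT-to-SOC dictionary
#'
#' Serialises a dictionary in the same format [read_meddra()] accepts, so
#' `read -> write -> read` is an identity on the entries.
#'
#' @param dict a `meddra_dictionary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meddra <- function(dict, path) {
  stopifnot(inherits(dict, "meddra_dictionary"))
  lines <- character(0)
  if (!is.na(dict$version)) lines <- sprintf("version: %s", dict$version)
  lines <- c(lines, paste(dict$entries$pt, dict$entries$soc, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.meddra_dictionary <- function(x, ...) {
  cat(sprintf("PT->SOC dictionary (version %s): %d PTs, %d SOCs\n",
              ifelse(is.na(x$version), "unversioned", x$version),
              nrow(x$entries), length(x$soc_list)))
  invisible(x)
}

#' Map preferred terms to their primary SOC
#'
#' Lookup is exact after case folding and whitespace trimming, because FAERS
#' PT strings vary in casing across quarters. Unmapped PTs are returned as
#' `NA` and tallied in the `n_unmapped` attribute; they are never silently
#' dropped -- downstream record builders carry the tally into their audit.
#'
#' @param dict a `meddra_dictionary`.
#' @param pt character vector of preferred terms.
#' @return character vector of SOC names (`NA` marks an unmapped PT) with
#'   attribute `n_unmapped`.
#' @export
map_pt <- function(dict, pt) {
  stopifnot(inherits(dict, "meddra_dictionary"))
  idx <- match(tolower(trimws(pt)), tolower(dict$entries$pt))
  soc <- dict$entries$soc[idx]
  attr(soc, "n_unmapped") <- sum(is.na(idx))
  soc
}

#' Dictionary bundled with the package
#'
#' A small PT-to-SOC dictionary covering the preferred terms emitted by the
#' synthetic report generator and appearing in the bundled mepolizumab
#' validation tables. It is a toy stand-in for a licensed MedDRA release,
#' sufficient for testing the pipeline end to end.
#'
#' @return a `meddra_dictionary`.
#' @export
toy_meddra <- function() {
  read_meddra(system.file("extdata", "meddra_toy.tsv", package = "pvsignal",
                          mustWork = TRUE))
}
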