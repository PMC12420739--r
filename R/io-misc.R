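#' Read a side-compound list
#'
#' @param path Plain-text file with one metabolite id per line; blank lines
#'   and `#` comments are ignored.
#' @return Character vector of ids.
#' @export
read_side_compounds <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Write a side-compound list
#'
#' @param side_compounds Character vector of ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_side_compounds <- function(side_compounds, path) {
  writeLines(sort(unique(side_compounds)), path)
  invisible(path)
}

#' Read a pathway category table
#'
#' @param path 2-column TSV with header columns `pathway_id` and `category`.
#' @return Tibble with `pathway_id`, `category`.
#' @export
read_pathway_categories <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      pathway_id = readr::col_character(),
      category = readr::col_character()
    )
  )
}

#' Write a pathway category table
#'
#' @param categories Tibble with `pathway_id`, `category`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_categories <- function(categories, path) {
  readr::write_tsv(categories[, c("pathway_id", "category")], path)
  invisible(path)
}

#' Read pathway sets from a GMT file
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#'
#' @param path GMT file path.
#' @return A `metabolite_pathway_sets` tibble (`pathway_id`, `metabolite`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- purrr::map_dfr(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("malformed GMT line (need name, description, members)")
    tibble(pathway_id = parts[[1]], metabolite = unique(parts[-(1:2)]))
  })
  structure(sets,
    class = c("metabolite_pathway_sets", class(sets)),
    side_compounds_included = NA
  )
}

#' Write pathway sets to a GMT file
#'
#' @param sets A `metabolite_pathway_sets` tibble.
#' @param path Output path.
#' @param description Second-column description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "pabench") {
  lst <- sets_as_list(sets)
  lines <- vapply(names(lst), function(nm) {
    paste(c(nm, description, lst[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
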