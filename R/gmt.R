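#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1], call. = FALSE)
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  lines <- mapply(function(name, genes, desc) {
    paste(c(name, desc, genes), collapse = "\t")
  }, names(sets), sets, rep_len(description, length(sets)))
  writeLines(lines, path)
  invisible(path)
}

#' The 19-gene human supragranular enriched (HSE) set
#'
#' Genes enriched in supragranular layers (II/III) of human cortex, where
#' most long-distance cortico-cortical projections originate. Shipped as a
#' GMT fixture with the package.
#'
#' @return character vector of 19 gene symbols.
#' @export
hse_genes <- function() {
  read_gmt(system.file("extdata", "hse.gmt", package = "transcortex"))[["HSE"]]
}
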