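#' Read and write the pipeline's tabular formats
#'
#' Plain-TSV round-trips for the wide tables the modules exchange (coverage,
#' genotypes, intensities, phased counts) and BED export for call sets.
#' Coordinates in BED output are 0-based half-open; TSV tables keep whatever
#' coordinate columns the tibble carries.
#'
#' @param x tibble to write.
#' @param path file path.
#' @return `read_pipeline_tsv` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_pipeline_tsv <- function(x, path) {
  x <- as.data.frame(x)
  list_cols <- vapply(x, is.list, logical(1))
  x[list_cols] <- lapply(x[list_cols], vapply, paste, character(1),
                         collapse = ",")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pipeline_tsv
#' @export
read_pipeline_tsv <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' @rdname write_pipeline_tsv
#' @param calls call tibble with `chrom`, `start`, `end` and a name-like
#'   column (`sample` or `call_id`).
#' @export
write_calls_bed <- function(calls, path) {
  name <- if ("sample" %in% names(calls)) calls$sample
          else calls$call_id %||% "."
  score <- if ("z" %in% names(calls)) round(calls$z, 3) else 0
  bed <- data.frame(chrom = calls$chrom, start = format(calls$start,
                                                        scientific = FALSE),
                    end = format(calls$end, scientific = FALSE),
                    name = name, score = score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
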