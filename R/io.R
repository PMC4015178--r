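# Flat-file interfaces: model parameter files (JSON or key-value text) and
# whitespace-delimited divergence matrices with state labels.

#' Read model parameters from a file
#'
#' Accepts either JSON (\code{{"pi": [...], "s": [...]}}) or flat key-value
#' text with lines such as \code{pi = 0.1 0.2 0.3 0.4}. \code{pi} is in
#' A, C, G, T order; \code{s} in AC, AG, AT, CG, CT, GT order.
#'
#' @param path file path.
#' @return A \linkS4class{SubstitutionModel}.
#' @export
readModelParameters <- function(path) {
  if (!file.exists(path)) stop("parameter file '", path, "' not found")
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  if (startsWith(first, "{")) {
    obj <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
    return(substitutionModel(obj$pi, obj$s))
  }
  vals <- list()
  for (line in txt) {
    line <- sub("#.*$", "", line)
    if (!grepl("=", line, fixed = TRUE)) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    vals[[key]] <- as.numeric(strsplit(trimws(kv[2L]), "[[:space:],]+")[[1L]])
  }
  if (is.null(vals$pi) || is.null(vals$s))
    stop("parameter file must define both 'pi' and 's'")
  substitutionModel(vals$pi, vals$s)
}

#' Write model parameters to a JSON file
#'
#' @param model a \linkS4class{SubstitutionModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeModelParameters <- function(model, path) {
  stopifnot(is(model, "SubstitutionModel"))
  jsonlite::write_json(list(pi = unname(model@pi), s = unname(model@s)),
                       path, digits = NA)
  invisible(path)
}

#' Read / write a divergence matrix
#'
#' Divergence matrices are stored as whitespace-delimited tables with a
#' header row and a leading column of state labels.
#'
#' @param path file path.
#' @return \code{readDivergenceMatrix}: a labelled numeric matrix.
#' @export
readDivergenceMatrix <- function(path) {
  if (!file.exists(path)) stop("divergence matrix file '", path, "' not found")
  tab <- read.table(path, header = TRUE, row.names = 1L,
                    check.names = FALSE)
  N <- as.matrix(tab)
  .check_divergence(N)
  N
}

#' @rdname readDivergenceMatrix
#' @param N a square divergence matrix.
#' @export
writeDivergenceMatrix <- function(N, path) {
  .check_divergence(N)
  if (is.null(rownames(N)))
    dimnames(N) <- list(NUCLEOTIDES[seq_len(nrow(N))],
                        NUCLEOTIDES[seq_len(ncol(N))])
  write.table(N, path, quote = FALSE, sep = "\t", col.names = NA)
  invisible(path)
}
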