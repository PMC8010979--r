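#' @keywords internal
"_PACKAGE"

# Fixed module color palette; order is part of the package contract so module
# names are reproducible across runs and platforms.
.module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
  "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
  "burlywood", "pink4", "darkolivegreen1", "thistle2", "chocolate2",
  "cornflowerblue", "aliceblue", "darkgray", "lavenderblush2"
)

module_color_names <- function(n) {
  if (n <= length(.module_palette)) {
    .module_palette[seq_len(n)]
  } else {
    c(.module_palette,
      paste0("module", seq.int(length(.module_palette) + 1L, n)))
  }
}

#' Two-sided p-value for a Pearson correlation via the t transform
#'
#' @param r correlation coefficient(s).
#' @param n number(s) of paired observations (must be > 2).
#' @return two-sided p-value(s) with `n - 2` degrees of freedom.
#' @export
cor_pvalue <- function(r, n) {
  if (any(n <= 2)) stop("need more than 2 paired observations")
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

# Column-wise Pearson correlation of paired matrices (same dims), one r per
# column. Constant columns yield NA.
paired_column_cor <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  xs <- scale(x)
  ys <- scale(y)
  r <- colSums(xs * ys) / (nrow(x) - 1)
  r[!is.finite(r)] <- NA_real_
  r
}

#' Write / read a numeric matrix as TSV (first column = row ids)
#'
#' @param x numeric matrix with row and column names.
#' @param path file path.
#' @param id_col name used for the id column header.
#' @return `read_matrix_tsv` returns the matrix with dimnames restored.
#' @export
write_matrix_tsv <- function(x, path, id_col = "sample_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
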