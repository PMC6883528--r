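#' Binned intra-chromosomal contact matrix
#'
#' A `contact_matrix` holds the symmetric binned contact map for one
#' chromosome of one sample, either as raw read-pair counts or as
#' normalized values. Unmappable bins are represented by `NA` rows and
#' columns, and every transform in the package propagates that mask.
#'
#' @param values symmetric numeric n x n matrix (counts or normalized
#'   values); `NA` entries mark unusable cells.
#' @param chrom chromosome label.
#' @param bin_size bin width in bp.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, chrom = "chrS", bin_size = 40000L) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("contact matrix must be square")
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE)))
    stop("contact matrix must be symmetric")
  if (bin_size <= 0) stop("bin_size must be positive")
  structure(
    list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
         values = unname(values)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  n <- n_bins(x)
  cat(sprintf("<contact_matrix> %s: %d bins of %d bp, %d NA bins\n",
              x$chrom, n, x$bin_size, length(na_bins(x))))
  invisible(x)
}

#' Number of bins in a contact matrix
#' @param cm a `contact_matrix`.
#' @export
n_bins <- function(cm) nrow(cm$values)

#' Indices of fully masked (NA) bins
#' @param cm a `contact_matrix`.
#' @return integer vector of bin indices (1-based) whose rows are all NA.
#' @export
na_bins <- function(cm) which(rowSums(!is.na(cm$values)) == 0L)

#' Mask bins of a contact matrix
#'
#' Sets the listed bins' rows and columns to `NA`.
#'
#' @param cm a `contact_matrix`.
#' @param bins integer bin indices (1-based).
#' @export
mask_bins <- function(cm, bins) {
  bins <- unique(as.integer(bins))
  if (length(bins)) {
    cm$values[bins, ] <- NA_real_
    cm$values[, bins] <- NA_real_
  }
  cm
}

#' Tally read pairs into a binned contact matrix
#'
#' Bins are 0-based half-open intervals `[k*bin_size, (k+1)*bin_size)` over
#' positions; a trailing partial bin is kept. Each pair is tallied once into
#' the symmetric matrix using the five-prime positions of its two ends.
#'
#' @param pairs data frame (or 2-column matrix) with 1-based positions
#'   `pos_a`, `pos_b` of the two read ends.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin width in bp (default 40 kb).
#' @param chrom chromosome label.
#' @return a `contact_matrix` of counts.
#' @export
bin_read_pairs <- function(pairs, chrom_length, bin_size = 40000L,
                           chrom = "chrS") {
  pairs <- as.matrix(as.data.frame(pairs)[, 1:2])
  if (nrow(pairs) && (any(pairs < 1) || any(pairs > chrom_length)))
    stop("read positions must lie in [1, chrom_length]")
  n <- bin_count(chrom_length, bin_size)
  bi <- floor((pairs[, 1] - 1) / bin_size) + 1L
  bj <- floor((pairs[, 2] - 1) / bin_size) + 1L
  m <- matrix(0, n, n)
  for (k in seq_along(bi)) {
    m[bi[k], bj[k]] <- m[bi[k], bj[k]] + 1
    if (bi[k] != bj[k]) m[bj[k], bi[k]] <- m[bj[k], bi[k]] + 1
  }
  contact_matrix(m, chrom = chrom, bin_size = bin_size)
}

#' Bins needed to tile a chromosome
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin width in bp.
#' @return number of bins (ceiling; trailing partial bin counts).
#' @export
bin_count <- function(chrom_length, bin_size = 40000L) {
  as.integer(ceiling(chrom_length / bin_size))
}

#' hg19 autosome lengths
#'
#' Chromosome lengths (bp) of the 22 human autosomes in the hg19 assembly,
#' used for genome-wide bin arithmetic.
#'
#' @return named integer vector, chr1..chr22.
#' @export
hg19_autosome_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430,
    chr4 = 191154276, chr5 = 180915260, chr6 = 171115067,
    chr7 = 159138663, chr8 = 146364022, chr9 = 141213431,
    chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
    chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
    chr19 = 59128983, chr20 = 63025520, chr21 = 48129895,
    chr22 = 51304566)
}

#' Total 40-kb bin count across the hg19 autosomes
#'
#' Tiles every autosome with fixed-width bins (trailing partial bin kept)
#' and sums the per-chromosome counts.
#'
#' @param bin_size bin width in bp (default 40 kb).
#' @export
autosome_bin_count <- function(bin_size = 40000L) {
  sum(vapply(hg19_autosome_lengths(), bin_count, integer(1),
             bin_size = bin_size))
}

#' Write a contact matrix as sparse triplets
#'
#' Upper triangle (including the diagonal) only, 0-based bin indices,
#' tab-separated columns `bin_i`, `bin_j`, `value`. NA and zero cells are
#' omitted.
#'
#' @param cm a `contact_matrix`.
#' @param path output file.
#' @export
write_triplets <- function(cm, path) {
  n <- n_bins(cm)
  idx <- which(upper.tri(cm$values, diag = TRUE) & !is.na(cm$values) &
                 cm$values != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                   value = cm$values[idx])
  df <- df[order(df$bin_i, df$bin_j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sparse-triplet contact matrix
#'
#' @param path triplet TSV (`bin_i`, `bin_j`, `value`; 0-based, upper
#'   triangle).
#' @param n_bins matrix dimension.
#' @inheritParams contact_matrix
#' @export
read_triplets <- function(path, n_bins, chrom = "chrS", bin_size = 40000L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- matrix(0, n_bins, n_bins)
  i <- df$bin_i + 1L
  j <- df$bin_j + 1L
  m[cbind(i, j)] <- df$value
  m[cbind(j, i)] <- df$value
  contact_matrix(m, chrom = chrom, bin_size = bin_size)
}

#' Write a per-bin track as bedGraph
#'
#' @param values per-bin scores (NA bins skipped).
#' @param path output file.
#' @param chrom chromosome label.
#' @param bin_size bin width in bp.
#' @export
write_bedgraph <- function(values, path, chrom = "chrS", bin_size = 40000L) {
  keep <- which(!is.na(values))
  df <- data.frame(chrom = chrom, start = (keep - 1L) * bin_size,
                   end = keep * bin_size, value = values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
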