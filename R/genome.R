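#' Genome builds
#'
#' A genome build is a data frame with columns `chrom` (character) and
#' `length` (integer bp), one row per chromosome, in karyotype order.
#' All interval arithmetic in the package (fraction of genome altered,
#' segment bounds checks) is performed against a build.
#'
#' @param name build name.
#' @param chromosomes data frame with columns `chrom` and `length`.
#' @return An object of class `genome_build`: a data frame with columns
#'   `chrom`, `length` and attribute `name`.
#' @examples
#' b <- genome_build("toy", data.frame(chrom = "1", length = 1e8))
#' genome_b37()
#' @export
genome_build <- function(name, chromosomes) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  chrom <- normalize_chrom(as.character(chromosomes$chrom))
  len <- as.numeric(chromosomes$length)
  if (anyDuplicated(chrom)) stop("duplicate chromosome names in build")
  if (any(!is.finite(len)) || any(len <= 0)) stop("chromosome lengths must be positive")
  out <- data.frame(chrom = chrom, length = len, stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("genome_build", "data.frame")
  out
}

# b37 / GRCh37 primary chromosome lengths, autosomes 1-22 plus X
.B37_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560
)

#' @rdname genome_build
#' @export
genome_b37 <- function() {
  genome_build("b37", data.frame(chrom = names(.B37_LENGTHS),
                                 length = unname(.B37_LENGTHS)))
}

#' Read a genome build from a two-column TSV
#'
#' @param path TSV with columns `chrom` and `length` (header required).
#' @param name build name; defaults to the file name.
#' @return A [genome_build()].
#' @export
read_genome_build <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(tab)))
    stop("genome build file must have columns 'chrom' and 'length'")
  genome_build(name, tab)
}

#' Normalise chromosome names
#'
#' Strips a leading "chr" prefix and maps "23" to "X" so that FACETS-style
#' numeric chromosome codes and UCSC-style names resolve to one namespace.
#'
#' @param x character vector of chromosome names.
#' @return normalised character vector.
#' @export
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x[x == "23"] <- "X"
  x
}

chrom_length <- function(build, chrom) {
  build$length[match(chrom, build$chrom)]
}
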