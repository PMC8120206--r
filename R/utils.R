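# Internal helpers shared across modules.

# GRCh38 autosome lengths rounded to the nearest megabase. Used by wgii()
# for bounds checking and by the synthetic generator to place variants.
.AUTOSOME_MB <- c(
  `1` = 249, `2` = 242, `3` = 198, `4` = 190, `5` = 182, `6` = 171,
  `7` = 159, `8` = 145, `9` = 138, `10` = 134, `11` = 135, `12` = 133,
  `13` = 114, `14` = 107, `15` = 102, `16` = 90, `17` = 83, `18` = 80,
  `19` = 59, `20` = 64, `21` = 47, `22` = 51
)

#' Autosome lengths used for segment bounds and variant placement
#'
#' GRCh38 autosome lengths rounded to the nearest megabase, named "1".."22".
#'
#' @return named numeric vector of lengths in bp.
#' @export
autosomeLengths <- function() .AUTOSOME_MB * 1e6

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.checkCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    .stopf("%s is missing required column(s): %s", what,
           paste(miss, collapse = ", "))
  invisible(TRUE)
}

.isCount <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)

# FNV-1a 32-bit hash of a character scalar; used for run-manifest config
# hashes so a manifest can be compared across runs without extra packages.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, split into
    # 16-bit halves so every intermediate stays exact in a double
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + (h1 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

# Population standard deviation (divides by n, not n - 1).
popSd <- function(x) sqrt(mean((x - mean(x))^2))

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Variant identity key: gene symbols are annotation only.
variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
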