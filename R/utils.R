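# Internal helpers shared across the package.

# bitmask <-> atom positions (1-based)
maskToAtoms <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L)
}

atomsToMask <- function(atoms) {
  if (length(atoms) == 0L) return(0L)
  sum(bitwShiftL(1L, as.integer(atoms) - 1L))
}

maskWeight <- function(mask) {
  vapply(mask, function(m) length(maskToAtoms(m)), integer(1))
}

# stable key for a labeling state
stateKey <- function(met, mask, mass = NA_integer_) {
  n <- max(length(met), length(mask), length(mass))
  met <- rep_len(met, n); mask <- rep_len(mask, n); mass <- rep_len(mass, n)
  out <- paste0(met, "#", mask)
  has <- !is.na(mass)
  out[has] <- paste0(out[has], "+", mass[has])
  out
}

# deterministic child seed derivation (kept below 2^31)
childSeed <- function(master, i) {
  (as.numeric(master) * 48271 + 7919 * as.numeric(i)) %% 2147483629 + 1
}

# parse "1,2,3" -> integer vector
parseAtomList <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(gsub("\\s", "", s), ",")[[1]])
}

formatAtomList <- function(a) paste(a, collapse = ",")

# sparse matrix from triplets with fixed dims
tripletMatrix <- function(i, j, x, nrow, ncol) {
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nrow, ncol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
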