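#' Canonical order of the 96 trinucleotide substitution motifs
#'
#' Substitution-major order over the six pyrimidine-strand substitutions
#' (C>A, C>G, C>T, T>A, T>C, T>G), with alphabetical 5' and 3' flanks within
#' each substitution — the layout used by published reference-signature
#' matrices. Labels look like `"A[C>A]A"`.
#'
#' @return character vector of length 96.
#' @export
sbs96_motifs <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  flanks <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(flanks, function(f5)
      paste0(f5, "[", s, "]", flanks)))))
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(s) {
  paste(rev(REVCOMP[strsplit(s, "")[[1]]]), collapse = "")
}

#' Map a single-base substitution to its 96-motif class
#'
#' The motif is the mutated base with one flanking base on each side. When the
#' reference base is a purine (A or G) the substitution and its context are
#' reverse-complemented so the mutated base is always a pyrimidine, making a
#' mutation and its reverse-strand description identical.
#'
#' @param chrom,pos coordinates, used only in error messages.
#' @param ref_base,alt_base single-base reference and alternate allele.
#' @param context3 3-mer centered on the mutated base; its center must equal
#'   `ref_base`.
#' @return motif label (e.g. `"A[C>T]A"`); use [motif_index()] for the
#'   position in the canonical order.
#' @examples
#' motif_of("1", 100, "C", "T", "ACA")  # "A[C>T]A"
#' motif_of("1", 100, "G", "T", "AGA")  # "T[C>A]T"
#' @export
motif_of <- function(chrom, pos, ref_base, alt_base, context3) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  context3 <- toupper(context3)
  loc <- paste0(chrom, ":", pos)
  if (nchar(ref_base) != 1 || nchar(alt_base) != 1)
    stop("not a single-nucleotide substitution at ", loc)
  if (!ref_base %in% names(REVCOMP) || !alt_base %in% names(REVCOMP))
    stop("non-ACGT allele at ", loc)
  if (ref_base == alt_base)
    stop("ref and alt identical at ", loc)
  if (nchar(context3) != 3 || substr(context3, 2, 2) != ref_base)
    stop("context center does not match ref base at ", loc)
  if (grepl("[^ACGT]", context3))
    stop("ambiguous base in context at ", loc)
  if (ref_base %in% c("A", "G")) {
    context3 <- revcomp(context3)
    ref_base <- REVCOMP[[ref_base]]
    alt_base <- REVCOMP[[alt_base]]
  }
  paste0(substr(context3, 1, 1), "[", ref_base, ">", alt_base, "]",
         substr(context3, 3, 3))
}

#' @rdname motif_of
#' @param motif motif label.
#' @return `motif_index`: integer position in [sbs96_motifs()].
#' @export
motif_index <- function(motif) {
  i <- match(motif, sbs96_motifs())
  if (any(is.na(i))) stop("unknown motif: ", motif[is.na(i)][1])
  i
}

#' Build per-sample 96-motif mutation catalogs
#'
#' Tallies single-nucleotide substitutions into the canonical 96-motif
#' catalog, one column per sample. Trinucleotide context comes either from a
#' `context` column in the mutation table or from a reference genome (named
#' sequences; FASTA path or Biostrings DNAStringSet). Records that are not
#' SNVs, have ambiguous bases, or whose context cannot be resolved are skipped
#' and logged in the `skipped` attribute.
#'
#' @param mutations data.frame with columns `sample`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `context` (3-mer). MAF-style column names
#'   (`Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#'   `Reference_Allele`, `Tumor_Seq_Allele2`) are also accepted.
#' @param genome optional context source when no `context` column is present:
#'   a FASTA file path or a `Biostrings::DNAStringSet` named by chromosome.
#' @param samples optional sample universe (catalogs are emitted, possibly
#'   all-zero, for each; defaults to the samples present in the table).
#' @return 96 x samples integer matrix with motif rownames, class
#'   `motif_catalog_matrix`; attribute `skipped` logs rejected records.
#' @export
build_catalogs <- function(mutations, genome = NULL, samples = NULL) {
  mutations <- normalize_mutation_columns(mutations)
  if (is.null(samples)) samples <- unique(mutations$sample)
  motifs <- sbs96_motifs()
  cat_mat <- matrix(0L, nrow = 96, ncol = length(samples),
                    dimnames = list(motifs, samples))
  if (nrow(mutations) == 0) {
    class(cat_mat) <- c("motif_catalog_matrix", class(cat_mat))
    attr(cat_mat, "skipped") <- empty_skip_log()
    return(cat_mat)
  }
  ctx <- if ("context" %in% names(mutations)) {
    toupper(mutations$context)
  } else {
    if (is.null(genome))
      stop("mutation table has no context column and no genome was given")
    extract_context(genome, mutations$chrom, mutations$pos)
  }
  skipped <- empty_skip_log()
  motif <- rep(NA_character_, nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    m <- tryCatch(motif_of(mutations$chrom[i], mutations$pos[i],
                           mutations$ref[i], mutations$alt[i], ctx[i]),
                  error = function(e) conditionMessage(e))
    if (m %in% motifs) motif[i] <- m
    else skipped <- rbind(skipped, data.frame(
      sample = mutations$sample[i], chrom = mutations$chrom[i],
      pos = mutations$pos[i], reason = m, stringsAsFactors = FALSE))
  }
  ok <- !is.na(motif)
  if (any(ok)) {
    tab <- table(factor(motif[ok], levels = motifs),
                 factor(mutations$sample[ok], levels = samples))
    cat_mat[] <- cat_mat + as.integer(tab)
  }
  class(cat_mat) <- c("motif_catalog_matrix", class(cat_mat))
  attr(cat_mat, "skipped") <- skipped
  cat_mat
}

empty_skip_log <- function() {
  data.frame(sample = character(), chrom = character(), pos = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

normalize_mutation_columns <- function(mutations) {
  maf_map <- c(Tumor_Sample_Barcode = "sample", Chromosome = "chrom",
               Start_Position = "pos", Reference_Allele = "ref",
               Tumor_Seq_Allele2 = "alt")
  hit <- names(maf_map) %in% names(mutations)
  if (any(hit))
    names(mutations)[match(names(maf_map)[hit], names(mutations))] <-
      maf_map[hit]
  need <- c("sample", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(mutations)))
    stop("mutation table needs columns: ", paste(need, collapse = ", "))
  mutations
}

extract_context <- function(genome, chrom, pos) {
  if (is.character(genome) && length(genome) == 1) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("Biostrings is required to read a FASTA context source")
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  vapply(seq_along(chrom), function(i) {
    seqs <- genome[[chrom[i]]]
    if (is.null(seqs) || pos[i] < 2 || pos[i] + 1 > length(seqs))
      return(NA_character_)
    as.character(Biostrings::subseq(seqs, pos[i] - 1, pos[i] + 1))
  }, character(1))
}

#' Validate a reference signature matrix
#'
#' @param refmat 96 x K numeric matrix; rownames must be the canonical motif
#'   order, columns are signatures with probabilities summing to 1.
#' @return the matrix, invisibly, after validation.
#' @export
validate_signature_matrix <- function(refmat) {
  if (nrow(refmat) != 96) stop("signature matrix must have 96 rows")
  if (is.null(rownames(refmat)) || !identical(rownames(refmat), sbs96_motifs()))
    stop("signature matrix rows must be in the canonical 96-motif order")
  if (any(refmat < 0)) stop("signature probabilities must be non-negative")
  if (any(abs(colSums(refmat) - 1) > 1e-6))
    stop("each signature column must sum to 1")
  invisible(refmat)
}

#' Fit signature exposures by non-negative least squares
#'
#' Solves `min || refmat %*% s - counts ||_2` subject to `s >= 0`
#' (Lawson–Hanson active set), returning exposures in mutation-count units
#' together with the L2 reconstruction residual. Deterministic for fixed
#' inputs.
#'
#' @param counts length-96 catalog vector (one column of [build_catalogs()]);
#'   names, when present, must match the canonical motif order.
#' @param refmat validated signature matrix (see
#'   [validate_signature_matrix()]).
#' @return list of class `exposure_fit`: `exposures` (named, non-negative),
#'   `residual` (L2 norm).
#' @export
fit_exposures <- function(counts, refmat) {
  validate_signature_matrix(refmat)
  if (length(counts) != 96) stop("catalog must have 96 motif counts")
  if (!is.null(names(counts)) && !identical(names(counts), sbs96_motifs()))
    stop("catalog motif order does not match the canonical order")
  if (all(counts == 0)) {
    s <- stats::setNames(numeric(ncol(refmat)), colnames(refmat))
    return(structure(list(exposures = s, residual = 0),
                     class = "exposure_fit"))
  }
  fit <- pracma::lsqnonneg(unclass(refmat), as.numeric(counts))
  s <- stats::setNames(fit$x, colnames(refmat))
  structure(list(exposures = s,
                 residual = sqrt(sum((refmat %*% s - counts)^2))),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  nz <- x$exposures[x$exposures > 0]
  cat("exposure_fit:", length(nz), "of", length(x$exposures),
      "signatures active; residual", format(x$residual, digits = 4), "\n")
  if (length(nz)) print(round(sort(nz, decreasing = TRUE), 2))
  invisible(x)
}

#' Fit exposures for every catalog column
#'
#' @param catalogs 96 x samples matrix from [build_catalogs()].
#' @param refmat reference signature matrix.
#' @return list with `exposures` (signatures x samples matrix) and
#'   `residuals` (per-sample L2 residual).
#' @export
fit_all_exposures <- function(catalogs, refmat) {
  fits <- lapply(seq_len(ncol(catalogs)), function(j)
    fit_exposures(stats::setNames(catalogs[, j], rownames(catalogs)), refmat))
  exposures <- vapply(fits, function(f) f$exposures, numeric(ncol(refmat)))
  exposures <- matrix(exposures, nrow = ncol(refmat),
                      dimnames = list(colnames(refmat), colnames(catalogs)))
  list(exposures = exposures,
       residuals = stats::setNames(vapply(fits, function(f) f$residual,
                                          numeric(1)), colnames(catalogs)))
}

#' Read / write a tab-delimited signature matrix
#'
#' First column holds motif labels in the standard bracket format; remaining
#' columns are signatures. Rows are reordered to the canonical motif order on
#' read.
#'
#' @param path file path.
#' @return 96 x K matrix with motif rownames.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  i <- match(sbs96_motifs(), rownames(m))
  if (any(is.na(i))) stop("signature matrix is missing motifs")
  m <- m[i, , drop = FALSE]
  validate_signature_matrix(m)
  m
}

#' @rdname read_signature_matrix
#' @param refmat matrix to write.
#' @export
write_signature_matrix <- function(refmat, path) {
  df <- data.frame(MutationType = rownames(refmat), refmat,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
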