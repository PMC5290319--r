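#' Build a variant_call_matrix from matched tumour-normal VCF files
#'
#' Each VCF contributes one tumour sample (and optionally a matched normal
#' sample identified by `normal_regex`). Variant identity is
#' (chromosome, position, ref, alt) with 1-based VCF positions, so the same
#' locus with different alternate alleles yields distinct variant rows.
#' Somatic filter: a variant is kept if, in every normal sample in which it
#' is covered, its allele fraction is below `normal_max_vaf`. Variants absent
#' from a tumour VCF get coverage 0 in that sample (panel dropout).
#'
#' Requires the `VariantAnnotation` package (Suggests); the VCFs must carry
#' the per-sample allelic depth (`AD`) genotype field.
#'
#' @param vcf_paths Character vector of VCF file paths.
#' @param sample_names Optional names for the tumour samples (default: the
#'   tumour sample name inside each VCF).
#' @param normal_regex Regular expression identifying normal samples by name.
#' @param normal_max_vaf Maximal allele fraction in the normal for a variant
#'   to be considered somatic.
#' @param patient_id Patient identifier.
#' @return A [variant_call_matrix()].
#' @export
read_vcf_pair <- function(vcf_paths, sample_names = NULL,
                          normal_regex = "(?i)normal",
                          normal_max_vaf = 0.02, patient_id = "patient") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_pair requires the VariantAnnotation package")
  per_file <- lapply(vcf_paths, read_one_vcf, normal_regex = normal_regex)
  if (!is.null(sample_names)) {
    if (length(sample_names) != length(per_file))
      stop("sample_names must match the number of VCF files")
    for (i in seq_along(per_file)) per_file[[i]]$tumor_name <- sample_names[i]
  }
  tn <- vapply(per_file, `[[`, character(1L), "tumor_name")
  if (anyDuplicated(tn)) tn <- make.unique(tn)

  keys <- unique(unlist(lapply(per_file, function(f) f$tab$key)))
  ref_of <- new.env(parent = emptyenv())
  for (f in per_file) {
    for (i in seq_len(nrow(f$tab))) {
      loc <- f$tab$locus[i]
      prev <- ref_of[[loc]]
      if (is.null(prev)) assign(loc, f$tab$ref[i], envir = ref_of)
      else if (!identical(prev, f$tab$ref[i]))
        stop("inconsistent reference alleles at locus ", loc,
             ": ", prev, " vs ", f$tab$ref[i])
    }
  }
  K <- matrix(0L, length(keys), length(per_file), dimnames = list(keys, tn))
  N <- K
  normal_bad <- character(0L)
  for (j in seq_along(per_file)) {
    tab <- per_file[[j]]$tab
    idx <- match(tab$key, keys)
    K[idx, j] <- tab$alt_reads
    N[idx, j] <- tab$depth
    if (!is.null(tab$normal_vaf)) {
      covered <- !is.na(tab$normal_vaf)
      normal_bad <- c(normal_bad,
                      tab$key[covered & tab$normal_vaf >= normal_max_vaf])
    }
  }
  somatic <- setdiff(keys, unique(normal_bad))
  if (!length(somatic)) stop("no somatic variants remain after normal filter")
  ann <- do.call(rbind, strsplit(somatic, "_"))
  variants <- data.frame(chrom = ann[, 1L], pos = as.integer(ann[, 2L]),
                         ref = ann[, 3L], alt = ann[, 4L],
                         stringsAsFactors = FALSE)
  variant_call_matrix(K[somatic, , drop = FALSE], N[somatic, , drop = FALSE],
                      patient_id = patient_id, variants = variants)
}

read_one_vcf <- function(path, normal_regex) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)  # one row per alt allele
  geno <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(geno))
    stop("VCF lacks the allelic depth (AD) genotype field: ", path)
  smp <- colnames(geno$AD)
  is_normal <- grepl(normal_regex, smp, perl = TRUE)
  if (all(is_normal)) stop("VCF has only normal samples: ", path)
  tumor <- smp[!is_normal][1L]
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  ad_col <- function(sample) {
    AD <- geno$AD
    if (length(dim(AD)) == 3L) {
      cbind(AD[, sample, 1L], AD[, sample, 2L])
    } else {
      ad <- AD[, sample]
      if (is.list(ad)) t(vapply(ad, function(v) {
        if (length(v) < 2L || anyNA(v)) c(NA_integer_, NA_integer_)
        else c(v[1L], v[2L])
      }, integer(2L)))
      else matrix(ad, ncol = 2L)
    }
  }
  adt <- ad_col(tumor)
  tab <- data.frame(key = paste(chrom, pos, ref, alt, sep = "_"),
                    locus = paste(chrom, pos, sep = "_"),
                    ref = ref,
                    alt_reads = as.integer(adt[, 2L]),
                    depth = as.integer(adt[, 1L] + adt[, 2L]),
                    stringsAsFactors = FALSE)
  normals <- smp[is_normal]
  if (length(normals)) {
    adn <- ad_col(normals[1L])
    dn <- adn[, 1L] + adn[, 2L]
    tab$normal_vaf <- ifelse(dn > 0, adn[, 2L] / dn, NA_real_)
  }
  tab <- tab[!is.na(tab$alt_reads) & !is.na(tab$depth), , drop = FALSE]
  tab <- tab[tab$alt_reads > 0, , drop = FALSE]
  list(tumor_name = tumor, tab = tab)
}
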