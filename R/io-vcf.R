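#' Construct a variant panel
#'
#' A variant panel is the package's container for a bi-allelic SNP genotype
#' matrix over a structured population: site table (0-based positions),
#' dosage matrix, per-copy haplotype matrices where phase is known, and a
#' sample-to-group map.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `ref`, `alt`
#'   (single nucleotides).
#' @param geno integer matrix sites x samples of alt-allele dosages
#'   (0/1/2, `NA` = missing); column names are sample ids.
#' @param groups named character vector mapping every sample id to a
#'   population group label.
#' @param hap1,hap2 optional 0/1/`NA` matrices (same shape as `geno`) giving
#'   the two chromosome copies where phase is known.
#' @param phased optional logical matrix: `TRUE` where the genotype is phased
#'   or homozygous (so the two copies are determined). Defaults to `TRUE` for
#'   homozygous calls and `FALSE` for heterozygotes when `hap1` is absent.
#' @return An object of class `variant_panel`.
#' @export
variant_panel <- function(sites, geno, groups, hap1 = NULL, hap2 = NULL,
                          phased = NULL) {
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stopf("site table missing column(s): %s", paste(miss, collapse = ", "))
  sites <- as.data.frame(sites)[, need]
  sites$pos <- as.integer(sites$pos)
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites)) stopf("geno rows (%d) != sites (%d)", nrow(geno), nrow(sites))
  if (is.null(colnames(geno))) stopf("geno must have sample column names")
  if (!all(geno %in% c(0L, 1L, 2L, NA))) stopf("genotype codes must be 0/1/2/NA")
  samples <- colnames(geno)
  missing_grp <- setdiff(samples, names(groups))
  if (length(missing_grp))
    stopf("samples missing from group map: %s", paste(missing_grp, collapse = ", "))
  groups <- groups[samples]

  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  geno <- geno[ord, , drop = FALSE]
  if (is.null(phased)) {
    phased <- !is.na(geno) & geno != 1L
    if (!is.null(hap1)) phased[] <- !is.na(hap1[ord, , drop = FALSE])
  } else {
    phased <- phased[ord, , drop = FALSE]
  }
  if (is.null(hap1)) {
    hap1 <- matrix(NA_integer_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
    hap2 <- hap1
    hom <- !is.na(geno) & geno != 1L
    hap1[hom] <- as.integer(geno[hom] / 2L)
    hap2[hom] <- as.integer(geno[hom] / 2L)
  } else {
    hap1 <- hap1[ord, , drop = FALSE]
    hap2 <- hap2[ord, , drop = FALSE]
  }
  structure(list(sites = sites, geno = geno, hap1 = hap1, hap2 = hap2,
                 phased = phased, samples = samples, groups = groups),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("variant_panel: %d sites x %d samples, %d group(s)\n",
              nrow(x$sites), length(x$samples), length(unique(x$groups))))
  invisible(x)
}

#' Read a bi-allelic SNP panel from VCF
#'
#' Reads a VCF (plain text or gzipped) with vcfR, keeping bi-allelic SNP
#' records only; multi-allelic sites and indels are skipped and counted
#' (`attr(, "n_skipped")`). GT fields are collapsed to alt-allele dosage;
#' phased heterozygotes (`a|b`) additionally populate the per-copy haplotype
#' matrices used by [haplotypes()]. VCF 1-based positions become 0-based.
#'
#' @param path VCF file.
#' @param group_map_path optional TSV with header columns `sample`, `group`
#'   covering every VCF sample; a VCF sample absent from the map is a hard
#'   error. When omitted, all samples are assigned group `"ALL"`.
#' @return A [variant_panel()].
#' @export
read_vcf <- function(path, group_map_path = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- grepl("^[ACGT]$", fix$REF) & grepl("^[ACGT]$", fix$ALT)
  n_skipped <- sum(!snp)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]
  samples <- colnames(gt)

  if (!is.null(group_map_path)) {
    gm <- read.table(group_map_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(gm)))
      stopf("group map needs columns 'sample' and 'group'")
    missing_grp <- setdiff(samples, gm$sample)
    if (length(missing_grp))
      stopf("VCF samples missing from group map: %s",
            paste(missing_grp, collapse = ", "))
    groups <- setNames(gm$group, gm$sample)[samples]
  } else {
    groups <- setNames(rep("ALL", length(samples)), samples)
  }

  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  a1[!a1 %in% c("0", "1")] <- NA
  a2[!a2 %in% c("0", "1")] <- NA
  h1 <- matrix(as.integer(a1), nrow(gt), ncol(gt))
  h2 <- matrix(as.integer(a2), nrow(gt), ncol(gt))
  geno <- h1 + h2
  phased <- !is.na(geno) & (sep == "|" | geno != 1L)
  het_unphased <- !is.na(geno) & geno == 1L & sep != "|"
  h1[het_unphased] <- NA_integer_
  h2[het_unphased] <- NA_integer_
  dimnames(geno) <- dimnames(h1) <- dimnames(h2) <- dimnames(phased) <-
    list(NULL, samples)

  out <- variant_panel(
    sites = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
                       ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    geno = geno, groups = groups, hap1 = h1, hap2 = h2, phased = phased
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a variant panel as plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotype fields; phased calls are
#' written `a|b`, unphased heterozygotes `0/1`, missing `./.`. Internal
#' 0-based positions become 1-based.
#'
#' @param panel a [variant_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "variant_panel"))
  n <- nrow(panel$sites)
  gt <- matrix("./.", n, length(panel$samples))
  ok <- !is.na(panel$geno)
  ph <- panel$phased & !is.na(panel$hap1) & !is.na(panel$hap2)
  gt[ok & !ph] <- c("0/0", "0/1", "1/1")[panel$geno[ok & !ph] + 1L]
  gt[ph] <- paste0(panel$hap1[ph], "|", panel$hap2[ph])
  dim(gt) <- c(n, length(panel$samples))
  body <- paste(panel$sites$chrom, panel$sites$pos + 1L, ".",
                panel$sites$ref, panel$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a sample-to-group map as TSV
#'
#' @param groups named character vector (names = sample ids).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(groups, path) {
  write.table(data.frame(sample = names(groups), group = unname(groups)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
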