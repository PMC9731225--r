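#' @importFrom utils read.table write.table packageVersion
NULL

.vcf_header <- function(sample_ids, info_lines, format_lines,
                        provenance = NULL) {
  c("##fileformat=VCFv4.2",
    paste0("##source=imputeval_", as.character(packageVersion("imputeval"))),
    if (!is.null(provenance))
      paste0("##imputeval_", names(provenance), "=", unlist(provenance)),
    "##contig=<ID=chr1>",
    info_lines, format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

#' Write a haplotype or genotype panel as VCF
#'
#' Phased haplotype panels are written with \code{"|"}-separated GT,
#' unphased genotype panels with \code{"/"}.  Internal 0-based positions
#' are emitted 1-based.  Provenance (seed, config hash) is recorded as
#' \code{##imputeval_*} header lines.
#'
#' @param panel \code{haplotype_panel} or \code{genotype_panel}.
#' @param path output file path.
#' @param provenance optional named list recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_panel_vcf <- function(panel, path, provenance = NULL) {
  s <- panel$sites
  info <- sprintf("AF=%.6g", s$af)
  if (inherits(panel, "haplotype_panel")) {
    n <- n_samples(panel)
    h <- panel$haplotypes
    a1 <- h[seq(1L, 2L * n, 2L), , drop = FALSE]
    a2 <- h[seq(2L, 2L * n, 2L), , drop = FALSE]
    sep <- if (panel$phased) "|" else "/"
    gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), sep,
                        ifelse(is.na(a2), ".", a2)), n)
  } else {
    g <- panel$geno
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g))
    gt[is.na(g)] <- "./."
  }
  if (!is.null(s$gpos)) info <- paste0(info, sprintf(";CM=%.8g", s$gpos))
  body <- cbind(s$contig, s$pos + 1L, ".", s$ref, s$alt, ".", "PASS",
                info, "GT", t(gt))
  lines <- c(.vcf_header(panel$sample_ids,
                         '##INFO=<ID=AF,Number=A,Type=Float,Description="Non-reference allele frequency">',
                         '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                         provenance),
             apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

.parse_info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

#' Read a VCF into a haplotype or genotype panel
#'
#' Biallelic SNV-or-indel records are kept; multi-allelic records are
#' skipped with a count (attribute \code{"n_skipped"}).  If every GT is
#' \code{"|"}-phased a \code{haplotype_panel} is returned, otherwise a
#' \code{genotype_panel}.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return panel object; attribute \code{"n_skipped"} counts skipped
#'   multi-allelic records.
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  gt <- v@gt[, -1L, drop = FALSE]
  gt <- sub(":.*$", "", gt)
  keep <- which(!multi)
  if (length(keep) == 0L) stop("no biallelic records in ", path)
  info <- v@fix[keep, "INFO"]
  gpos <- suppressWarnings(as.numeric(.parse_info_field(info, "CM")))
  sites <- data.frame(contig = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]) - 1L,
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                      stringsAsFactors = FALSE)
  if (!all(is.na(gpos))) sites$gpos <- gpos
  gt <- gt[keep, , drop = FALSE]
  phased <- all(grepl("|", gt, fixed = TRUE))
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  to_int <- function(x) { x[x == "."] <- NA; as.integer(x) }
  samples <- colnames(v@gt)[-1L]
  if (phased) {
    n <- length(samples)
    h <- matrix(0L, 2L * n, nrow(sites))
    h[seq(1L, 2L * n, 2L), ] <- t(matrix(to_int(a1), nrow(gt)))
    h[seq(2L, 2L * n, 2L), ] <- t(matrix(to_int(a2), nrow(gt)))
    out <- haplotype_panel(sites, h, samples, phased = TRUE)
  } else {
    g <- t(matrix(to_int(a1) + to_int(a2), nrow(gt)))
    out <- genotype_panel(sites, g, samples)
  }
  attr(out, "n_skipped") <- sum(multi)
  out
}

#' Write a dosage set as VCF (GT/DS/HDS, INFO R2/AF/TYPED)
#'
#' Dosages are serialized at 3 decimals (VCF convention); the optional
#' sidecar empirical-dose VCF carries the leave-one-out haplotype
#' dosages at typed sites, the input meta-imputation consumes.
#'
#' @param ds a \code{dosage_set}.
#' @param path output VCF path.
#' @param empirical_path optional path for the leave-one-out sidecar.
#' @param provenance optional named list recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_dosage_vcf <- function(ds, path, empirical_path = NULL,
                             provenance = NULL) {
  s <- ds$sites
  n <- length(ds$sample_ids)
  af <- colMeans(ds$hds)
  info <- sprintf("AF=%.6g;R2=%.3f%s", af, ds$est_r2,
                  ifelse(s$typed, ";TYPED", ""))
  if (!is.null(s$gpos)) info <- paste0(info, sprintf(";CM=%.8g", s$gpos))
  h1 <- ds$hds[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- ds$hds[seq(2L, 2L * n, 2L), , drop = FALSE]
  fmt <- matrix(sprintf("%d|%d:%.3f:%.3f,%.3f", round(h1), round(h2),
                        ds$ds, h1, h2), n)
  body <- cbind(s$contig, s$pos + 1L, ".", s$ref, s$alt, ".", "PASS",
                info, "GT:DS:HDS", t(fmt))
  lines <- c(.vcf_header(
    ds$sample_ids,
    c('##INFO=<ID=AF,Number=A,Type=Float,Description="Estimated alt allele frequency">',
      '##INFO=<ID=R2,Number=1,Type=Float,Description="Estimated imputation r2 (info score)">',
      '##INFO=<ID=TYPED,Number=0,Type=Flag,Description="Site was genotyped on the array">'),
    c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Rounded imputed genotype">',
      '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Diploid dosage">',
      '##FORMAT=<ID=HDS,Number=2,Type=Float,Description="Haplotype dosages">'),
    provenance),
    apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  if (!is.null(empirical_path)) {
    ti <- ds$typed_idx
    st <- s[ti, , drop = FALSE]
    l1 <- ds$loo[seq(1L, 2L * n, 2L), , drop = FALSE]
    l2 <- ds$loo[seq(2L, 2L * n, 2L), , drop = FALSE]
    fmt2 <- matrix(sprintf("%.3f,%.3f", l1, l2), n)
    info2 <- sprintf("AF=%.6g", colMeans(ds$loo))
    if (!is.null(st$gpos)) info2 <- paste0(info2, sprintf(";CM=%.8g", st$gpos))
    body2 <- cbind(st$contig, st$pos + 1L, ".", st$ref, st$alt, ".", "PASS",
                   info2, "LDS", t(fmt2))
    lines2 <- c(.vcf_header(
      ds$sample_ids,
      '##INFO=<ID=AF,Number=A,Type=Float,Description="Mean leave-one-out dosage">',
      '##FORMAT=<ID=LDS,Number=2,Type=Float,Description="Leave-one-out haplotype dosages at typed sites">',
      provenance),
      apply(body2, 1L, paste, collapse = "\t"))
    writeLines(lines2, empirical_path)
  }
  invisible(path)
}

#' Read a dosage VCF (and optional empirical sidecar) back
#'
#' @param path dosage VCF written by \code{\link{write_dosage_vcf}}.
#' @param empirical_path optional sidecar with leave-one-out dosages.
#' @param panel_id identifier for the resulting set.
#' @return A \code{dosage_set} (with \code{loo = NULL} when no sidecar
#'   is given).
#' @export
read_dosage_vcf <- function(path, empirical_path = NULL, panel_id = "ref") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  info <- v@fix[, "INFO"]
  gpos <- suppressWarnings(as.numeric(.parse_info_field(info, "CM")))
  sites <- data.frame(contig = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]) - 1L,
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      typed = grepl("(^|;)TYPED(;|$)", info),
                      stringsAsFactors = FALSE)
  if (!all(is.na(gpos))) sites$gpos <- gpos
  est_r2 <- as.numeric(.parse_info_field(info, "R2"))
  hds_str <- vcfR::extract.gt(v, element = "HDS")
  samples <- colnames(v@gt)[-1L]
  n <- length(samples); S <- nrow(sites)
  hds <- matrix(0, 2L * n, S)
  for (j in seq_len(n)) {
    parts <- strsplit(hds_str[, j], ",", fixed = TRUE)
    hds[2L * j - 1L, ] <- as.numeric(vapply(parts, `[`, character(1), 1L))
    hds[2L * j, ] <- as.numeric(vapply(parts, `[`, character(1), 2L))
  }
  ds_m <- hds[seq(1L, 2L * n, 2L), , drop = FALSE] +
    hds[seq(2L, 2L * n, 2L), , drop = FALSE]
  loo <- NULL
  typed_idx <- which(sites$typed)
  if (!is.null(empirical_path)) {
    ve <- vcfR::read.vcfR(empirical_path, verbose = FALSE)
    lds <- vcfR::extract.gt(ve, element = "LDS")
    Tn <- nrow(lds)
    loo <- matrix(0, 2L * n, Tn)
    for (j in seq_len(n)) {
      parts <- strsplit(lds[, j], ",", fixed = TRUE)
      loo[2L * j - 1L, ] <- as.numeric(vapply(parts, `[`, character(1), 1L))
      loo[2L * j, ] <- as.numeric(vapply(parts, `[`, character(1), 2L))
    }
  }
  structure(list(sites = sites, hds = hds, ds = ds_m, loo = loo,
                 est_r2 = est_r2, typed_idx = typed_idx,
                 sample_ids = samples, panel_id = panel_id,
                 n_dropped_typed = 0L),
            class = "dosage_set")
}

#' Write an array manifest TSV (1-based positions)
#' @param manifest an \code{array_manifest}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest_tsv <- function(manifest, path) {
  df <- data.frame(contig = manifest$contig, pos = manifest$pos + 1L,
                   ref = manifest$ref, alt = manifest$alt,
                   design_pop = attr(manifest, "design_pop"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an array manifest TSV
#' @param path manifest TSV with columns contig, pos (1-based), ref,
#'   alt, design_pop.
#' @return An \code{array_manifest}.
#' @export
read_manifest_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  required <- c("contig", "pos", "ref", "alt")
  if (!all(required %in% names(df)))
    stop("manifest must have columns: ", paste(required, collapse = ", "))
  out <- data.frame(contig = df$contig, pos = as.integer(df$pos) - 1L,
                    ref = df$ref, alt = df$alt, stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            design_pop = if (!is.null(df$design_pop)) df$design_pop[1L] else NA,
            target_density = nrow(out),
            class = c("array_manifest", "data.frame"))
}

#' Read a BED file of half-open 0-based intervals
#'
#' @param path BED path (first three columns contig, start, end).
#' @return data.frame with columns contig, start, end.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L || is.na(suppressWarnings(as.integer(p[2L]))) ||
        is.na(suppressWarnings(as.integer(p[3L]))))
      stop("malformed BED line ", i, ": ", lines[i])
  }
  data.frame(contig = vapply(parts, `[`, character(1), 1L),
             start = as.integer(vapply(parts, `[`, character(1), 2L)),
             end = as.integer(vapply(parts, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Read an external site list (TSV with 1-based pos, or VCF)
#'
#' @param path site TSV (columns contig, pos, ref, alt) or a VCF.
#' @return data.frame with 0-based \code{pos}, suitable for the QC
#'   presence filter.
#' @export
read_site_list <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                         dimnames = list(NULL, names(fix)))
    return(data.frame(contig = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]) - 1L,
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE))
  }
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse site list ", path, ": ",
                             conditionMessage(e)))
  required <- c("contig", "pos", "ref", "alt")
  if (!all(required %in% names(df)))
    stop("site list must have columns: ", paste(required, collapse = ", "))
  df$pos <- as.integer(df$pos) - 1L
  df[, required]
}
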