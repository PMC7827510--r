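#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads biallelic SNP records from a VCF 4.x file (plain or bgzipped) into a
#' [geno_matrix()]. Indels, multi-allelic records and records whose REF/ALT
#' are not single A/C/G/T bases are skipped and counted (the count is stored
#' in the `n_skipped` attribute and reported via a message). Missing
#' genotypes (`./.`) and half-calls (`./1`) are mapped to `NA`; phased (`|`)
#' and unphased (`/`) separators are both accepted. Samples absent from
#' `group_map` are dropped.
#'
#' A per-site functional effect class (synonymous, nonsynonymous, stopgain,
#' stoploss, frameshift, other) is read, never computed, from the INFO key
#' named by `effect_key`.
#'
#' @param path VCF file path.
#' @param group_map named character vector mapping sample id to `"A"` or
#'   `"B"`, e.g. from [read_group_file()].
#' @param effect_key INFO key holding the effect class (default
#'   `"ANN_CLASS"`).
#'
#' @return A [geno_matrix()] with attribute `n_skipped`.
#' @export
read_vcf <- function(path, group_map, effect_key = "ANN_CLASS") {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  vcf_samples <- colnames(gt)[-1]
  absent <- setdiff(names(group_map), vcf_samples)
  if (length(absent) > 0) {
    stop("group_map samples absent from VCF header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep_samples <- vcf_samples[vcf_samples %in% names(group_map)]

  bases <- c("A", "C", "G", "T")
  snp <- fix$REF %in% bases & fix$ALT %in% bases
  snp[is.na(snp)] <- FALSE
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped,
            " non-biallelic-SNP record(s)")
  }
  if (!any(snp)) stop("no usable biallelic SNP records in ", path,
                      call. = FALSE)

  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, c("FORMAT", keep_samples), drop = FALSE]

  gt_codes <- extract_gt_field(gt)
  dosage <- gt_to_dosage(gt_codes)

  effect <- rep(NA_character_, nrow(fix))
  if (!is.null(fix$INFO)) {
    hit <- stringr::str_match(fix$INFO,
                              paste0("(?:^|;)", effect_key, "=([^;]+)"))[, 2]
    effect <- ifelse(is.na(hit), NA_character_, hit)
  }

  sites <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    effect_class = effect
  )
  gm <- geno_matrix(t(dosage), sites, keep_samples, group_map)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

# GT field (before the first ':') for each record x sample
extract_gt_field <- function(gt) {
  body <- gt[, -1, drop = FALSE]
  codes <- sub(":.*$", "", body)
  dim(codes) <- dim(body)
  colnames(codes) <- colnames(body)
  codes
}

# "0/1", "0|1", "./." etc -> dosage 0/1/2/NA; half-calls are missing
gt_to_dosage <- function(codes) {
  norm <- gsub("\\|", "/", codes)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  d <- map[norm]
  dim(d) <- dim(codes)
  colnames(d) <- colnames(codes)
  d
}

#' Read phased haplotypes from a VCF
#'
#' Every GT field must be phased (`|`) and fully called; the first offending
#' record aborts with its `chrom:pos`. Only biallelic SNP records are used.
#' One [hap_matrix()] is returned per chromosome, with two haplotypes per
#' retained sample.
#'
#' @inheritParams read_vcf
#' @return Named list of [hap_matrix()], keyed by chromosome.
#' @export
read_phased <- function(path, group_map) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  vcf_samples <- colnames(gt)[-1]
  absent <- setdiff(names(group_map), vcf_samples)
  if (length(absent) > 0) {
    stop("group_map samples absent from VCF header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep_samples <- vcf_samples[vcf_samples %in% names(group_map)]

  bases <- c("A", "C", "G", "T")
  snp <- fix$REF %in% bases & fix$ALT %in% bases
  snp[is.na(snp)] <- FALSE
  if (!any(snp)) stop("no usable biallelic SNP records in ", path,
                      call. = FALSE)
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, c("FORMAT", keep_samples), drop = FALSE]
  codes <- extract_gt_field(gt)

  ok <- grepl("^[01]\\|[01]$", codes)
  dim(ok) <- dim(codes)
  if (!all(ok)) {
    first <- which(!ok, arr.ind = TRUE)[1, ]
    stop("unphased or missing genotype at ", fix$CHROM[first[1]], ":",
         fix$POS[first[1]], " (sample ", keep_samples[first[2]], ", GT '",
         codes[first[1], first[2]], "')", call. = FALSE)
  }

  a1 <- as.integer(substr(codes, 1, 1))
  a2 <- as.integer(substr(codes, 3, 3))
  dim(a1) <- dim(codes); dim(a2) <- dim(codes)

  out <- list()
  for (chr in unique(fix$CHROM)) {
    idx <- which(fix$CHROM == chr)
    n <- length(keep_samples)
    hap <- matrix(0L, nrow = 2L * n, ncol = length(idx))
    for (s in seq_len(n)) {
      hap[2L * s - 1L, ] <- a1[idx, s]
      hap[2L * s, ] <- a2[idx, s]
    }
    out[[chr]] <- hap_matrix(hap, as.numeric(fix$POS[idx]), chr,
                             rep(keep_samples, each = 2L))
  }
  out
}

#' Filter sites by minor allele frequency, missingness and chromosome
#'
#' Thresholds are computed on the retained sample set only (samples were
#' already restricted at read time), so dropping samples then filtering
#' equals filtering then dropping. Site order is preserved.
#'
#' @param gm a [geno_matrix()].
#' @param min_maf minimum minor allele frequency over non-missing calls
#'   (0 to 0.5).
#' @param max_missing maximum fraction of samples with a missing call.
#' @param chroms optional chromosome whitelist.
#'
#' @return A filtered [geno_matrix()].
#' @export
filter_sites <- function(gm, min_maf = 0, max_missing = 1 - 1e-9,
                         chroms = NULL) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, max_missing >= 0, max_missing < 1)
  g <- gm$geno
  n <- nrow(g)
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(alt, 1 - alt)
  miss_frac <- 1 - n_called / n
  keep <- !is.na(maf) & maf >= min_maf & miss_frac <= max_missing
  if (!is.null(chroms)) keep <- keep & gm$sites$chrom %in% chroms
  if (!any(keep)) stop("all sites removed by filters", call. = FALSE)
  geno_matrix(g[, keep, drop = FALSE], gm$sites[keep, , drop = FALSE],
              gm$samples, gm$groups)
}

#' Write a windowed statistic track to TSV or BED
#'
#' Window coordinates are 0-based half-open internally and are written as
#' such (matching BED). The TSV carries a `#` comment header recording the
#' statistic name and any normalization constants, then columns
#' `chrom/start/end/n_snps/value` at full precision. [read_track()] inverts
#' the TSV form exactly.
#'
#' @param track tibble with columns `chrom`, `start`, `end`, `n_snps`,
#'   `value` (a window track from e.g. [window_mean()]).
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (nrow(track) == 0) stop("refusing to write an empty track",
                             call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    meta <- c(
      paste0("#statistic=", track_stat(track) %||% "unknown"),
      if (!is.null(attr(track, "genomewide_mean")))
        paste0("#genomewide_mean=",
               format(attr(track, "genomewide_mean"), digits = 17)),
      if (!is.null(attr(track, "genomewide_sd")))
        paste0("#genomewide_sd=",
               format(attr(track, "genomewide_sd"), digits = 17))
    )
    writeLines(meta, con)
    writeLines(paste("chrom", "start", "end", "n_snps", "value",
                     sep = "\t"), con)
    writeLines(paste(track$chrom,
                     format(track$start, scientific = FALSE, trim = TRUE),
                     format(track$end, scientific = FALSE, trim = TRUE),
                     track$n_snps,
                     vapply(track$value, format_full, character(1)),
                     sep = "\t"), con)
  } else {
    writeLines(paste(track$chrom,
                     format(track$start, scientific = FALSE, trim = TRUE),
                     format(track$end, scientific = FALSE, trim = TRUE),
                     paste0(track_stat(track) %||% "stat", "_",
                            seq_len(nrow(track))),
                     vapply(track$value, format_full, character(1)),
                     sep = "\t"), con)
  }
  invisible(path)
}

format_full <- function(x) {
  if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE,
                                 trim = TRUE)
}

#' Read a track TSV written by [write_track()]
#'
#' @param path TSV path.
#' @return A window-track tibble with statistic metadata restored.
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric", "numeric",
                                          "integer", "numeric"),
                           na.strings = "NA")
  tr <- tibble::as_tibble(tab)
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0("#", key, "="))]
    if (length(hit) == 0) NULL else sub(paste0("^#", key, "="), "", hit[1])
  }
  attr(tr, "statistic") <- get_meta("statistic")
  gm <- get_meta("genomewide_mean"); gs <- get_meta("genomewide_sd")
  if (!is.null(gm)) attr(tr, "genomewide_mean") <- as.numeric(gm)
  if (!is.null(gs)) attr(tr, "genomewide_sd") <- as.numeric(gs)
  tr
}

#' Read a two-column sample-to-group file
#'
#' Plain TSV, no header: `sample<TAB>A|B`.
#'
#' @param path file path.
#' @return Named character vector mapping sample to group.
#' @export
read_group_file <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("sample", "group"),
                           colClasses = "character")
  stats::setNames(tab$group, tab$sample)
}

#' Read gene annotation from BED or GFF3
#'
#' BED input is taken as 0-based half-open; GFF3 (1-based inclusive) is
#' converted to the package's internal 0-based half-open convention. For
#' GFF3, only rows of `feature_type` are kept and the gene id/name are taken
#' from the `ID`/`Name` attributes.
#'
#' @param path annotation path; format inferred from the extension unless
#'   `format` is given.
#' @param format `"bed"` or `"gff3"`.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return Tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open).
#' @export
read_genes <- function(path, format = NULL, feature_type = "gene") {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  format <- match.arg(format, c("bed", "gff3"))
  if (format == "bed") {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    tibble::tibble(
      gene_id = if (ncol(tab) >= 4) as.character(tab[[4]])
                else paste0("gene", seq_len(nrow(tab))),
      gene_name = if (ncol(tab) >= 4) as.character(tab[[4]])
                  else paste0("gene", seq_len(nrow(tab))),
      chrom = as.character(tab[[1]]),
      start = as.numeric(tab[[2]]),
      end = as.numeric(tab[[3]]),
      strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else "."
    )
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE,
                             quote = "")
    tab <- tab[tab[[3]] == feature_type, , drop = FALSE]
    attr_get <- function(attrs, key) {
      hit <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
      hit
    }
    ids <- attr_get(tab[[9]], "ID")
    nm <- attr_get(tab[[9]], "Name")
    tibble::tibble(
      gene_id = ifelse(is.na(ids), paste0("gene", seq_len(nrow(tab))), ids),
      gene_name = ifelse(is.na(nm), ids, nm),
      chrom = as.character(tab[[1]]),
      start = as.numeric(tab[[4]]) - 1,
      end = as.numeric(tab[[5]]),
      strand = as.character(tab[[7]])
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

track_stat <- function(track) attr(track, "statistic", exact = TRUE)

set_track_stat <- function(track, name) {
  attr(track, "statistic") <- name
  track
}
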