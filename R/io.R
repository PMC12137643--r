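#' Read a VCF into the pipeline's data model
#'
#' Parses a VCF 4.x file into a [snp_data()] container. Only biallelic SNP
#' records are kept; multiallelic and indel records are skipped and counted.
#' Per-call DP and GQ are captured when the FORMAT carries them, the QUAL
#' column is stored as the variant-level allele quality, and filter-stage
#' flags written by [write_vcf()] (INFO key `SF`) are restored.
#'
#' @param path VCF file (plain text or gzip).
#' @param want_phase if `TRUE` and every non-missing genotype uses the `|`
#'   separator, the haplotype matrix is populated.
#' @return A `snp_data` object with attribute `n_skipped` (count of
#'   non-biallelic-SNP records dropped).
#' @export
read_vcf <- function(path, want_phase = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(structure(snp_data(empty_variant_table(),
                              matrix(integer(), 0, 0)),
                     n_skipped = 0L))
  }
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  }
  vcf <- vcf[snp, ]
  fix <- fix[snp, , drop = FALSE]

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (any(grepl("^[0-9.]+(/[0-9.]+){2,}$", gt_raw[!is.na(gt_raw)]))) {
    stop("unsupported record: ploidy other than 2 in GT field")
  }
  a1 <- substr(gt_raw, 1, 1)
  sep <- substr(gt_raw, 2, 2)
  a2 <- substr(gt_raw, 3, 3)
  miss <- is.na(gt_raw) | a1 == "." | a2 == "."
  # vcfR returns variants x samples; we carry samples x variants
  dosage <- matrix(ifelse(t(miss), NA_integer_,
                          suppressWarnings(as.integer(t(a1)) + as.integer(t(a2)))),
                   nrow = ncol(gt_raw),
                   dimnames = list(colnames(gt_raw), NULL))

  num_mat <- function(el) {
    m <- suppressWarnings(vcfR::extract.gt(vcf, element = el, as.numeric = TRUE))
    if (is.null(m) || all(is.na(m))) NULL else t(m)
  }
  dp <- num_mat("DP")
  gq <- num_mat("GQ")

  phased <- NULL
  if (want_phase && all(sep[!miss] == "|") && any(!miss)) {
    n <- ncol(gt_raw)
    phased <- matrix(NA_integer_, nrow = 2L * n, ncol = nrow(gt_raw))
    h1 <- t(ifelse(miss, NA, suppressWarnings(as.integer(a1))))
    h2 <- t(ifelse(miss, NA, suppressWarnings(as.integer(a2))))
    phased[seq(1, 2 * n, 2), ] <- h1
    phased[seq(2, 2 * n, 2), ] <- h2
    rownames(phased) <- paste0(rep(colnames(gt_raw), each = 2), c("_h1", "_h2"))
  }

  info <- ifelse(is.na(fix$INFO), "", fix$INFO)
  sf <- rep("", nrow(fix))
  has_sf <- grepl("(^|;)SF=", info)
  if (any(has_sf)) {
    sf[has_sf] <- gsub(",", ";", sub(".*SF=([^;]*).*", "\\1", info[has_sf]))
  }
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    stage_flags = sf, stringsAsFactors = FALSE)

  structure(snp_data(variants, dosage, dp = dp, gq = gq, phased = phased),
            n_skipped = n_skipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), stage_flags = character(),
             stringsAsFactors = FALSE)
}

#' Write a `snp_data` object as VCF 4.2
#'
#' Emits GT (phased with `|` when haplotypes are present), DP and GQ when
#' available, QUAL from the variant-level quality, and the stage flags as
#' the INFO key `SF` (comma-separated; [read_vcf()] converts back).
#'
#' @param x a `snp_data` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  v <- x$variants
  n <- n_samples(x)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SF,Number=1,Type=String,Description=\"Filter-stage flags\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (n > 0) c("FORMAT", rownames(x$dosage)))
  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(v) > 0) {
    fmt <- paste(c("GT", if (!is.null(x$dp)) "DP", if (!is.null(x$gq)) "GQ"),
                 collapse = ":")
    sep <- if (is.null(x$phased)) "/" else "|"
    gt <- matrix("./.", n, nrow(v))
    if (is.null(x$phased)) {
      gt[x$dosage == 0] <- paste0("0", sep, "0")
      gt[x$dosage == 1] <- paste0("0", sep, "1")
      gt[x$dosage == 2] <- paste0("1", sep, "1")
    } else {
      h1 <- x$phased[seq(1, 2 * n, 2), , drop = FALSE]
      h2 <- x$phased[seq(2, 2 * n, 2), , drop = FALSE]
      ok <- !is.na(h1) & !is.na(h2)
      gt[ok] <- paste0(h1[ok], sep, h2[ok])
    }
    cells <- gt
    if (!is.null(x$dp)) {
      cells <- matrix(paste(cells, ifelse(is.na(x$dp), ".", x$dp), sep = ":"),
                      n, nrow(v))
    }
    if (!is.null(x$gq)) {
      cells <- matrix(paste(cells, ifelse(is.na(x$gq), ".", x$gq), sep = ":"),
                      n, nrow(v))
    }
    info <- ifelse(v$stage_flags == "", ".",
                   paste0("SF=", gsub(";", ",", v$stage_flags)))
    qual <- if ("qual" %in% names(v)) ifelse(is.na(v$qual), ".", v$qual) else "."
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, "PASS", info,
                  fmt, apply(cells, 2, paste, collapse = "\t"), sep = "\t")
    if (n == 0) {
      body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, "PASS", info,
                    sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a pedigree table
#'
#' CSV with header `individual,sire,dam,relation_type`. `relation_type` is
#' `cross` (sexual cross, up to two named parents) or `sport` (clonal bud
#' mutation, exactly one named parent). Empty/NA parent fields mean
#' founder/unknown. The pedigree must be acyclic.
#'
#' @param path CSV file path.
#' @return A validated data.frame of class `pedigree_table`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("individual", "sire", "dam", "relation_type")
  if (!all(needed %in% names(ped))) {
    stop("pedigree file must have header: ", paste(needed, collapse = ","))
  }
  ped$sire[ped$sire %in% c("", "NA", ".")] <- NA
  ped$dam[ped$dam %in% c("", "NA", ".")] <- NA
  validate_pedigree(ped)
}

#' Validate a pedigree data.frame
#' @param ped data.frame with columns individual, sire, dam, relation_type.
#' @return `ped` with class `pedigree_table`, topologically sortable.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$individual)) {
    stop("duplicate individual id(s): ",
         paste(unique(ped$individual[duplicated(ped$individual)]),
               collapse = ", "))
  }
  sport <- ped$relation_type == "sport"
  bad <- sport & (is.na(ped$sire) == is.na(ped$dam))
  if (any(bad)) {
    stop("sport rows must name exactly one parent: ",
         paste(ped$individual[bad], collapse = ", "))
  }
  pedigree_topo_order(ped)  # errors on cycle
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Topological order of a pedigree (parents before offspring)
#' @param ped pedigree data.frame.
#' @return character vector of individual IDs in a valid processing order;
#'   founders (rows with no named parents, plus parents never listed as
#'   individuals) come first. Errors on a cycle, listing its members.
#' @export
pedigree_topo_order <- function(ped) {
  ids <- ped$individual
  parents <- lapply(seq_len(nrow(ped)), function(i) {
    p <- c(ped$sire[i], ped$dam[i])
    p[!is.na(p) & p %in% ids]
  })
  names(parents) <- ids
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  order_out <- character(0)
  visit <- function(id, stack) {
    if (state[[id]] == 2L) return(invisible())
    if (state[[id]] == 1L) {
      cyc <- c(stack[which(stack == id):length(stack)], id)
      stop("pedigree cycle: ", paste(cyc, collapse = " -> "))
    }
    state[[id]] <<- 1L
    for (p in parents[[id]]) visit(p, c(stack, id))
    state[[id]] <<- 2L
    order_out <<- c(order_out, id)
  }
  for (id in ids) visit(id, character(0))
  extern <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ids)
  c(extern, order_out)
}

#' Known trait names for the phenotype table
#' @export
KNOWN_TRAITS <- c("SSC", "pH", "TA", "sucrose", "glucose", "fructose",
                  "sorbitol", "malate", "citrate", "quinate", "shikimate",
                  "flowering_date")

#' Read a phenotype table
#'
#' Tab-separated with header `accession`, `trait`, `year`, `value`.
#' `flowering_date` values are day-of-year integers; other traits are
#' numeric measurements. Unknown trait names are kept with a warning.
#'
#' @param path TSV file path.
#' @return data.frame with one row per (accession, trait, year).
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("accession", "trait", "year", "value")
  if (!all(needed %in% names(ph))) {
    stop("phenotype file must have header: ", paste(needed, collapse = "\t"))
  }
  unknown <- setdiff(unique(ph$trait), KNOWN_TRAITS)
  if (length(unknown)) {
    warning("unknown trait name(s) kept: ", paste(unknown, collapse = ", "))
  }
  key <- paste(ph$accession, ph$trait, ph$year)
  if (anyDuplicated(key)) stop("duplicate (accession, trait, year) rows")
  ph$value <- as.numeric(ph$value)
  ph
}

#' Read gene models from GFF3 (plus optional reference FASTA)
#'
#' Builds the annotation container used by [annotate_regions()] and
#' [annotate_effects()]: a gene table and a CDS-segment table grouped by
#' mRNA. mRNAs whose concatenated CDS length is not divisible by 3 are
#' flagged (`frame_ok = FALSE`), not rejected.
#'
#' @param path GFF3 file.
#' @param fasta optional reference FASTA path (needed for effect
#'   annotation).
#' @return A list of class `gene_annotation` with elements `genes`
#'   (gene_id, chrom, start, end, strand), `cds` (gene_id, mrna_id, chrom,
#'   start, end, strand, phase), `mrna` (mrna_id, gene_id, frame_ok) and
#'   `seq` (a `DNAStringSet` or NULL).
#' @export
read_gff <- function(path, fasta = NULL) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  get_id <- function(d) as.character(d$ID)
  genes <- df[df$type == "gene", , drop = FALSE]
  genes_tab <- data.frame(gene_id = get_id(genes),
                          chrom = as.character(genes$seqnames),
                          start = genes$start, end = genes$end,
                          strand = as.character(genes$strand),
                          stringsAsFactors = FALSE)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  mrna_parent <- vapply(mrna$Parent, function(p) as.character(p)[1], "")
  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_parent <- vapply(cds$Parent, function(p) as.character(p)[1], "")
  mrna_gene <- stats::setNames(mrna_parent, get_id(mrna))
  cds_tab <- data.frame(mrna_id = cds_parent,
                        gene_id = unname(mrna_gene[cds_parent]),
                        chrom = as.character(cds$seqnames),
                        start = cds$start, end = cds$end,
                        strand = as.character(cds$strand),
                        phase = cds$phase,
                        stringsAsFactors = FALSE)
  cds_tab <- cds_tab[order(cds_tab$mrna_id, cds_tab$start), , drop = FALSE]
  len_by_mrna <- tapply(cds_tab$end - cds_tab$start + 1L, cds_tab$mrna_id, sum)
  mrna_tab <- data.frame(mrna_id = get_id(mrna),
                         gene_id = unname(mrna_parent),
                         stringsAsFactors = FALSE)
  mrna_tab$frame_ok <- (unname(len_by_mrna[mrna_tab$mrna_id]) %% 3L) == 0L
  mrna_tab$frame_ok[is.na(mrna_tab$frame_ok)] <- FALSE
  if (any(!mrna_tab$frame_ok)) {
    warning(sum(!mrna_tab$frame_ok),
            " mRNA(s) with CDS length not divisible by 3 flagged")
  }
  seq <- if (!is.null(fasta)) Biostrings::readDNAStringSet(fasta) else NULL
  if (!is.null(seq)) names(seq) <- sub("\\s.*", "", names(seq))
  structure(list(genes = genes_tab, cds = cds_tab, mrna = mrna_tab,
                 seq = seq),
            class = "gene_annotation")
}

#' Read pairwise IBD segments in RefinedIBD format
#'
#' Nine tab-separated columns: sample1, hap1, sample2, hap2, chrom, start,
#' end, LOD, length_cM. Haplotype indices are collapsed to the sample-pair
#' level: for each (pair, chrom) the union of the reported intervals is
#' taken. Rows with start > end are rejected with a warning.
#'
#' @param path segment file.
#' @param min_lod optional LOD floor; rows below it are dropped.
#' @return data.frame of class `ibd_segments` with columns `sample_a`,
#'   `sample_b` (canonically ordered), `chrom`, `start`, `end`, `score`.
#' @export
read_refined_ibd <- function(path, min_lod = NULL) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 9) stop("expected 9 columns of RefinedIBD output")
  names(d)[1:9] <- c("sample1", "hap1", "sample2", "hap2", "chrom",
                     "start", "end", "lod", "cm")
  bad <- d$start > d$end
  if (any(bad)) {
    warning(sum(bad), " segment(s) with start > end rejected")
    d <- d[!bad, , drop = FALSE]
  }
  if (!is.null(min_lod)) d <- d[d$lod >= min_lod, , drop = FALSE]
  seg <- data.frame(sample_a = pmin(d$sample1, d$sample2),
                    sample_b = pmax(d$sample1, d$sample2),
                    chrom = as.character(d$chrom),
                    start = as.integer(d$start), end = as.integer(d$end),
                    score = d$lod, stringsAsFactors = FALSE)
  merge_pair_segments(seg)
}

## Union of intervals per (sample_a, sample_b, chrom); scores are summed
## over the merged pieces (support).
merge_pair_segments <- function(seg) {
  if (nrow(seg) == 0) {
    seg <- seg[0, , drop = FALSE]
    class(seg) <- c("ibd_segments", "data.frame")
    return(seg)
  }
  key <- paste(seg$sample_a, seg$sample_b, seg$chrom, sep = "\r")
  out <- do.call(rbind, lapply(split(seg, key), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    runs <- merge_intervals(g$start, g$end)
    data.frame(sample_a = g$sample_a[1], sample_b = g$sample_b[1],
               chrom = g$chrom[1], start = runs$start, end = runs$end,
               score = vapply(seq_len(nrow(runs)), function(i) {
                 sum(g$score[g$start <= runs$end[i] & g$end >= runs$start[i]])
               }, 0), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_a, out$sample_b, out$chrom, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ibd_segments", "data.frame")
  out
}

## Merge sorted (by start) closed intervals that overlap or touch.
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  rs <- re <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      rs <- c(rs, ms); re <- c(re, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(rs, ms), end = c(re, me))
}
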