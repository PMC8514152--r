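# Readers and writers for the plain-text formats the pipeline touches:
# PLINK PED/MAP, a minimal VCF subset, Oxford GEN/SAMPLE, 3-column genetic
# maps, and array annotation CSVs.  All coordinates are 1-based.

#' Read a PLINK PED/MAP pair
#'
#' Allele letters are converted to counts of "allele 1" (`allele_b`): the
#' first allele letter encountered in file order at a site becomes
#' `allele_a`, the second distinct letter `allele_b`.  `0 0` is missing.
#' Sites observed with a single letter keep `allele_b = NA` until
#' harmonization supplies the other allele.
#'
#' @param ped_path,map_path file paths.
#' @param source dataset tag stored in the site table.
#' @return a [geno_dataset()].
#' @export
read_pedmap <- function(ped_path, map_path, source = basename(ped_path)) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (!ncol(map) %in% c(3L, 4L))
    stop("MAP file must have 3 or 4 columns")
  if (ncol(map) == 3L) map <- cbind(map[, 1:2], "0", map[, 3])
  names(map) <- c("chrom", "site_id", "cm", "pos")
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  geno <- matrix(NA_integer_, n, m)
  a_mat <- matrix(NA_character_, n, m)  # first allele per genotype
  b_mat <- matrix(NA_character_, n, m)
  ind <- data.frame(individual_id = character(n), population = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop(sprintf("ragged PED line %d: %d fields, expected %d",
                   i, length(f), 6L + 2L * m))
    ind$individual_id[i] <- f[2]
    ind$population[i] <- f[1]
    al <- f[-(1:6)]
    a_mat[i, ] <- al[seq(1L, 2L * m, by = 2L)]
    b_mat[i, ] <- al[seq(2L, 2L * m, by = 2L)]
  }
  allele_a <- rep(NA_character_, m)
  allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    obs <- c(rbind(a_mat[, j], b_mat[, j]))   # file order within site
    obs <- obs[obs != "0"]
    u <- unique(obs)
    if (length(u) > 2L)
      stop(sprintf("triallelic site %s: alleles %s", map$site_id[j],
                   paste(u, collapse = "/")))
    if (length(u) >= 1L) allele_a[j] <- u[1]
    if (length(u) == 2L) allele_b[j] <- u[2]
    miss <- a_mat[, j] == "0" | b_mat[, j] == "0"
    cnt <- (a_mat[, j] == allele_b[j]) + (b_mat[, j] == allele_b[j])
    cnt[is.na(cnt)] <- 0L   # monomorphic site: all calls are allele_a
    cnt[miss] <- NA_integer_
    geno[, j] <- as.integer(cnt)
  }
  sites <- site_table(map$chrom, as.integer(map$pos), map$site_id,
                      allele_a, allele_b, source = source)
  geno_dataset(sites, ind, geno)
}

#' Write a PLINK PED/MAP pair
#'
#' @param ds a `geno_ds`; sites with `allele_b = NA` are written as
#'   homozygous `allele_a`.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_pedmap <- function(ds, ped_path, map_path) {
  s <- ds$sites
  utils::write.table(data.frame(s$chrom, s$site_id, 0, s$pos),
                     map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  g <- ds$genotypes
  n <- nrow(g); m <- ncol(g)
  lines <- character(n)
  a <- s$allele_a; b <- ifelse(is.na(s$allele_b), s$allele_a, s$allele_b)
  for (i in seq_len(n)) {
    gi <- g[i, ]
    # heterozygotes as "a b": file-order allele assignment is then stable
    # under a read/write cycle
    a1 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, b, a))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, b, a))
    lines[i] <- paste(ds$individuals$population[i],
                      ds$individuals$individual_id[i],
                      0, 0, 0, -9,
                      paste(c(rbind(a1, a2)), collapse = " "))
  }
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a minimal VCF
#'
#' Supports the column subset CHROM POS ID REF ALT QUAL FILTER INFO FORMAT
#' with per-sample `GT[:GQ]`.  Only biallelic SNP records are retained;
#' genotypes with `GQ < min_gq` are set missing.  Indels and multiallelic
#' records are dropped and counted.
#'
#' @param vcf_path file path.
#' @param min_gq minimum Phred genotype quality; calls below it become
#'   missing (default 20).
#' @param source dataset tag.
#' @return list with elements `dataset` (a `geno_ds`) and `tally`
#'   (named counts: `input`, `retained`, `indels`, `multiallelic`, `other`).
#' @export
read_vcf_minimal <- function(vcf_path, min_gq = 20, source = basename(vcf_path)) {
  lines <- readLines(vcf_path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("malformed VCF header: missing ##fileformat line")
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr)) stop("malformed VCF header: missing #CHROM line")
  hdr <- hdr[1]
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stop("malformed VCF header: no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]

  tally <- c(input = length(body), retained = 0L, indels = 0L,
             multiallelic = 0L, other = 0L)
  keep <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols)) stop("malformed VCF record: field count")
    ref <- f[4]; alt <- f[5]
    if (grepl(",", alt, fixed = TRUE)) { tally["multiallelic"] <- tally["multiallelic"] + 1L; next }
    if (nchar(ref) != 1L || nchar(alt) != 1L) { tally["indels"] <- tally["indels"] + 1L; next }
    if (!ref %in% BASES || !alt %in% BASES) { tally["other"] <- tally["other"] + 1L; next }
    keep[[length(keep) + 1L]] <- f
  }
  tally["retained"] <- length(keep)

  m <- length(keep); n <- length(samples)
  geno <- matrix(NA_integer_, n, m)
  qual <- matrix(NA_real_, n, m)
  chrom <- pos <- id <- ref <- alt <- character(m)
  for (j in seq_len(m)) {
    f <- keep[[j]]
    chrom[j] <- f[1]; pos[j] <- f[2]
    id[j] <- if (f[3] == ".") paste0(f[1], "_", f[2]) else f[3]
    ref[j] <- f[4]; alt[j] <- f[5]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt); gq_i <- match("GQ", fmt)
    if (is.na(gt_i)) stop("VCF record without GT field")
    for (i in seq_len(n)) {
      sub <- strsplit(f[9 + i], ":", fixed = TRUE)[[1]]
      gt <- sub[gt_i]
      al <- strsplit(gt, "[/|]")[[1]]
      if (length(al) == 2L && !any(al == ".")) {
        geno[i, j] <- sum(al == "1")
        if (!is.na(gq_i) && gq_i <= length(sub) && sub[gq_i] != ".") {
          q <- as.numeric(sub[gq_i])
          qual[i, j] <- q
          if (q < min_gq) geno[i, j] <- NA_integer_
        }
      }
    }
  }
  sites <- site_table(chrom, as.integer(pos), id,
                      allele_a = ref, allele_b = alt, source = source)
  ind <- data.frame(individual_id = samples, population = source,
                    stringsAsFactors = FALSE)
  list(dataset = geno_dataset(sites, ind, geno, qual), tally = tally)
}

#' Write Oxford GEN/SAMPLE files
#'
#' One GEN line per site: `site_id site_id pos allele_a allele_b` followed
#' by three genotype probabilities per individual (order: hom `allele_a`,
#' het, hom `allele_b`), fixed 5-decimal format.
#'
#' @param dres a `dosage_result` (see [impute_dataset()]).
#' @param prefix output path prefix; writes `<prefix>.gen`, `<prefix>.sample`.
#' @return invisibly, the two paths.
#' @export
write_gen_sample <- function(dres, prefix) {
  p <- cbind(as.vector(dres$p0), as.vector(dres$p1), as.vector(dres$p2))
  if (any(p < -1e-9 | p > 1 + 1e-9))
    stop("genotype probabilities outside [0,1]")
  s <- dres$sites
  n <- nrow(dres$p0); m <- ncol(dres$p0)
  lines <- character(m)
  for (j in seq_len(m)) {
    probs <- rbind(dres$p0[, j], dres$p1[, j], dres$p2[, j])
    lines[j] <- paste(s$site_id[j], s$site_id[j], s$pos[j],
                      s$allele_a[j], s$allele_b[j],
                      paste(sprintf("%.5f", as.vector(probs)), collapse = " "))
  }
  gen_path <- paste0(prefix, ".gen")
  writeLines(lines, gen_path)
  sample_path <- paste0(prefix, ".sample")
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(dres$individuals$individual_id,
                     dres$individuals$individual_id, "0")),
             sample_path)
  invisible(c(gen_path, sample_path))
}

#' Read Oxford GEN/SAMPLE files
#'
#' @param prefix path prefix written by [write_gen_sample()].
#' @return a `dosage_result` (without Info scores, which are recomputed
#'   with [info_score()] if needed).
#' @export
read_gen_sample <- function(prefix) {
  gen <- readLines(paste0(prefix, ".gen"))
  smp <- readLines(paste0(prefix, ".sample"))
  ids <- vapply(strsplit(smp[-(1:2)], " "), `[`, character(1), 1L)
  n <- length(ids); m <- length(gen)
  p0 <- p1 <- p2 <- matrix(NA_real_, n, m)
  chrom <- rep("1", m); pos <- integer(m); id <- a <- b <- character(m)
  for (j in seq_len(m)) {
    f <- strsplit(gen[j], " ", fixed = TRUE)[[1]]
    if (length(f) != 5L + 3L * n) stop("GEN line field count mismatch")
    id[j] <- f[1]; pos[j] <- as.integer(f[3]); a[j] <- f[4]; b[j] <- f[5]
    pr <- as.numeric(f[-(1:5)])
    p0[, j] <- pr[seq(1L, 3L * n, by = 3L)]
    p1[, j] <- pr[seq(2L, 3L * n, by = 3L)]
    p2[, j] <- pr[seq(3L, 3L * n, by = 3L)]
  }
  sites <- site_table(chrom, pos, id, a, b, source = "gen")
  dosage_result(sites,
                data.frame(individual_id = ids, population = NA_character_,
                           stringsAsFactors = FALSE),
                p0, p1, p2, info = NULL, validate = FALSE)
}

#' Read a 3-column genetic map
#'
#' Whitespace-separated columns: position (bp), rate (cM/Mb), cumulative
#' genetic position (cM).  A non-numeric first line is treated as a header.
#'
#' @param path file path.
#' @param chrom chromosome label to attach (single-chromosome files).
#' @return a `genetic_map`: data.frame with `chrom`, `pos`, `rate`, `cum`.
#' @export
read_genetic_map <- function(path, chrom = "1") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) lines <- lines[-1]
  f <- do.call(rbind, lapply(strsplit(trimws(lines), "[ \t]+"), as.numeric))
  if (ncol(f) != 3L) stop("genetic map must have 3 columns")
  genetic_map(chrom, f[, 1], f[, 2], f[, 3])
}

#' Construct a genetic map
#'
#' @param chrom chromosome label.
#' @param pos bp positions, strictly increasing.
#' @param rate recombination rate, cM/Mb, non-negative.
#' @param cum cumulative genetic position, cM, non-decreasing.
#' @return a `genetic_map` data.frame.
#' @export
genetic_map <- function(chrom, pos, rate, cum) {
  if (any(diff(pos) <= 0)) stop("map positions must be strictly increasing")
  if (any(diff(cum) < 0)) stop("cumulative cM must be non-decreasing")
  if (any(rate < 0)) stop("map rates must be non-negative")
  structure(data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                       rate = as.numeric(rate), cum = as.numeric(cum),
                       stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

#' Uniform-rate genetic map
#'
#' @param chrom_length_bp chromosome length.
#' @param rate_cm_per_mb constant rate (default 1 cM/Mb).
#' @param chrom chromosome label.
#' @return a `genetic_map`.
#' @export
uniform_genetic_map <- function(chrom_length_bp, rate_cm_per_mb = 1,
                                chrom = "1") {
  genetic_map(chrom, pos = c(1, chrom_length_bp), rate = rate_cm_per_mb,
              cum = c(0, (chrom_length_bp - 1) / 1e6 * rate_cm_per_mb))
}

#' Interpolate genetic position
#'
#' Piecewise-linear between map points, constant beyond the ends.
#'
#' @param map a `genetic_map`.
#' @param pos bp positions.
#' @return genetic positions in cM.
#' @export
interpolate_cm <- function(map, pos) {
  stats::approx(map$pos, map$cum, xout = pos, rule = 2, ties = "ordered")$y
}

# Inverse lookup: cM -> bp (used to place simulated crossovers).
interpolate_bp <- function(map, cm) {
  stats::approx(map$cum, map$pos, xout = cm, rule = 2, ties = "ordered")$y
}

#' Write an annotation CSV
#'
#' Columns: site_id, chrom, pos, allele_a, allele_b, flank_up, flank_down.
#'
#' @param sites a site table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_annotation_csv <- function(sites, path) {
  utils::write.csv(sites[, c("site_id", "chrom", "pos", "allele_a",
                             "allele_b", "flank_up", "flank_down")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation CSV
#'
#' @param path file written by [write_annotation_csv()].
#' @param source dataset tag.
#' @return a site table.
#' @export
read_annotation_csv <- function(path, source = basename(path)) {
  df <- utils::read.csv(path, colClasses = "character")
  site_table(df$chrom, as.integer(df$pos), df$site_id, df$allele_a,
             df$allele_b, df$flank_up, df$flank_down, source = source)
}
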