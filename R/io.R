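#' Fixed-size genomic bins over a region
#'
#' @param chrom Chromosome name.
#' @param length_bp Region length in bp (the region starts at 0); the last
#'   bin may be shorter.
#' @param bin_size Bin size in bp.
#' @return Tibble with `chrom`, `start` (0-based, inclusive), `end`
#'   (exclusive) and `index` (0-based, consecutive).
#' @examples
#' genomic_bins("2L", 10000, 2000)
#' @export
genomic_bins <- function(chrom, length_bp, bin_size) {
  bin_size <- check_count(bin_size, "bin_size")
  length_bp <- check_count(length_bp, "length_bp")
  starts <- seq(0L, length_bp - 1L, by = bin_size)
  tibble(
    chrom = chrom,
    start = as.integer(starts),
    end = as.integer(pmin(starts + bin_size, length_bp)),
    index = seq_along(starts) - 1L
  )
}

#' Read a sparse triplet contact matrix
#'
#' Two tab/space-delimited dialects are auto-detected from the column count:
#' `(i, j, count)` with integer bin indices, or
#' `(chrom, start1, chrom, start2, count)` with bp coordinates converted to
#' indices via `bins`. Lower-triangle entries are folded onto the upper
#' triangle; a symmetric duplicate whose count disagrees is an error. When
#' `bins` is supplied, the full dense upper-triangle enumeration (diagonal
#' included) of the region is returned with absent pairs set to zero: an
#' m-bin region yields m(m+1)/2 pair rows.
#'
#' @param path Text file of triplets (no header).
#' @param bins Optional bin tibble from [genomic_bins()]; triggers dense
#'   zero-filled enumeration and coordinate-dialect conversion.
#' @param bin_size Bin size in bp; required for the coordinate dialect when
#'   `bins` is absent.
#' @return Tibble with 0-based `i`, `j` (i <= j) and integer `y`.
#' @export
read_contact_matrix <- function(path, bins = NULL, bin_size = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    raw <- tibble(i = integer(), j = integer(), y = integer())
  } else {
    fields <- strsplit(trimws(lines), "[\t ]+")
    ncols <- lengths(fields)
    if (length(unique(ncols)) != 1) {
      abort(sprintf("mixed triplet dialects: line %d has %d fields, line 1 has %d",
                    which(ncols != ncols[1])[1], ncols[which(ncols != ncols[1])[1]],
                    ncols[1]))
    }
    if (!ncols[1] %in% c(3L, 5L)) {
      abort("triplet file must have 3 (i j count) or 5 (chrom start chrom start count) columns")
    }
    if (ncols[1] == 3L) {
      m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 3,
                  byrow = TRUE)
      bad <- which(rowSums(is.na(m)) > 0)
      if (length(bad)) abort(sprintf("non-numeric triplet at line %d", bad[1]))
      raw <- tibble(i = m[, 1], j = m[, 2], y = m[, 3])
    } else {
      if (is.null(bin_size) && !is.null(bins)) {
        bin_size <- max(bins$end - bins$start)
      }
      if (is.null(bin_size)) abort("coordinate dialect needs `bins` or `bin_size`")
      s1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
      s2 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
      y <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
      bad <- which(is.na(s1) | is.na(s2) | is.na(y))
      if (length(bad)) abort(sprintf("non-numeric field at line %d", bad[1]))
      raw <- tibble(i = s1 %/% bin_size, j = s2 %/% bin_size, y = y)
    }
    bad <- which(raw$y < 0 | raw$y != floor(raw$y))
    if (length(bad)) {
      abort(sprintf("negative or non-integer count at line %d", bad[1]))
    }
    bad <- which(raw$i < 0 | raw$j < 0 | raw$i != floor(raw$i) |
                 raw$j != floor(raw$j))
    if (length(bad)) abort(sprintf("invalid bin index at line %d", bad[1]))
    # canonicalize to upper triangle and merge symmetric duplicates
    raw <- mutate(raw,
                  ii = pmin(.data$i, .data$j),
                  jj = pmax(.data$i, .data$j))
    raw <- summarise(group_by(raw, i = .data$ii, j = .data$jj),
                     n_counts = dplyr::n_distinct(.data$y),
                     y = .data$y[1], .groups = "drop")
    if (any(raw$n_counts > 1)) {
      bad <- raw[raw$n_counts > 1, ]
      abort(sprintf("conflicting counts for symmetric pair (%d, %d)",
                    bad$i[1], bad$j[1]))
    }
    raw <- select(raw, "i", "j", "y")
    raw <- mutate(raw, i = as.integer(.data$i), j = as.integer(.data$j),
                  y = as.integer(.data$y))
  }
  if (is.null(bins)) return(arrange(raw, .data$i, .data$j))
  m <- nrow(bins)
  dense <- dense_pairs(m)
  out <- left_join(dense, raw, by = c("i", "j"))
  out$y[is.na(out$y)] <- 0L
  stray <- dplyr::anti_join(raw, dense, by = c("i", "j"))
  if (nrow(stray) > 0) {
    abort(sprintf("pair (%d, %d) outside the %d-bin region", stray$i[1],
                  stray$j[1], m))
  }
  out
}

# All upper-triangle (i <= j) 0-based index pairs of an m-bin region,
# diagonal included: m(m+1)/2 rows.
dense_pairs <- function(m) {
  i <- rep(0:(m - 1L), times = m:1L)
  j <- unlist(lapply(0:(m - 1L), function(a) a:(m - 1L)))
  tibble(i = as.integer(i), j = as.integer(j))
}

#' Per-bin GC fraction from a FASTA file
#'
#' GC fraction is (#G + #C) / (#A + #C + #G + #T) per bin; ambiguous bases
#' are excluded from the denominator. A bin with no unambiguous base gets
#' `pseudocount`.
#'
#' @param fasta Path to a (multi-)FASTA file.
#' @param bins Bin tibble from [genomic_bins()].
#' @param pseudocount Value assigned to all-ambiguous bins (default 0.5).
#' @return Numeric vector of GC fractions, one per bin row.
#' @export
compute_gc_track <- function(fasta, bins, pseudocount = 0.5) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chrom <- unique(bins$chrom)
  missing <- setdiff(chrom, names(seqs))
  if (length(missing)) {
    abort(sprintf("chromosome `%s` not found in FASTA", missing[1]))
  }
  out <- numeric(nrow(bins))
  for (ch in chrom) {
    sel <- which(bins$chrom == ch)
    sq <- seqs[[ch]]
    starts <- pmin(bins$start[sel] + 1L, length(sq))
    ends <- pmin(bins$end[sel], length(sq))
    views <- Biostrings::Views(sq, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(views, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- (freq[, "G"] + freq[, "C"]) / denom
    gc[denom == 0] <- pseudocount
    out[sel] <- gc
  }
  out
}

# readr-based interval readers with line-numbered validation ------------------

read_bed_intervals <- function(path, n_fields = 3) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track|browser)", trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t")
  bad <- which(lengths(fields) < n_fields)
  if (length(bad)) {
    abort(sprintf("malformed interval at line %d: expected >= %d tab-separated fields",
                  lineno[bad[1]], n_fields))
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end < start)
  if (length(bad)) {
    abort(sprintf("malformed interval coordinates at line %d", lineno[bad[1]]))
  }
  tibble(chrom = chrom, start = start, end = end,
         extra = if (max(lengths(fields)) >= 4)
           vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
         else NA_character_,
         .line = lineno)
}

read_gff_intervals <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t")
  bad <- which(lengths(fields) < 8)
  if (length(bad)) {
    abort(sprintf("malformed GFF record at line %d: expected >= 8 tab-separated fields",
                  lineno[bad[1]]))
  }
  chrom <- vapply(fields, `[`, "", 1)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5)))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad)) {
    abort(sprintf("malformed GFF coordinates at line %d", lineno[bad[1]]))
  }
  # GFF is 1-based inclusive; internal representation is 0-based half-open
  tibble(chrom = chrom, start = start1 - 1L, end = end1, .line = lineno)
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = df$end)  # 1-based inclusive
  )
}

bins_to_granges <- function(bins) {
  GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(start = bins$start + 1L, end = bins$end)
  )
}

#' Per-bin interval counts (e.g. transposable elements)
#'
#' Counts, per bin, the annotation intervals overlapping the bin by at least
#' 1 bp. BED input is 0-based half-open; GFF/GFF3 input is 1-based
#' inclusive; the dialect is chosen by `format` or guessed from the file
#' extension.
#'
#' @param annotation Path to a BED or GFF file.
#' @param bins Bin tibble from [genomic_bins()].
#' @param format `"auto"`, `"bed"` or `"gff"`.
#' @return Integer vector of per-bin counts.
#' @export
compute_interval_track <- function(annotation, bins,
                                   format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.txt)?$", annotation, ignore.case = TRUE))
      "gff" else "bed"
  }
  iv <- if (format == "gff") read_gff_intervals(annotation)
        else read_bed_intervals(annotation)
  if (nrow(iv) == 0) return(rep(0L, nrow(bins)))
  GenomicRanges::countOverlaps(bins_to_granges(bins), intervals_to_granges(iv),
                               minoverlap = 1L)
}

#' Per-bin mean signal from a bedGraph file
#'
#' Coverage-weighted mean score per bin; uncovered bases contribute score 0.
#' Overlapping bedGraph intervals are rejected as ambiguous.
#'
#' @param bedgraph Path to a bedGraph file (0-based half-open, 4th column
#'   numeric score).
#' @param bins Bin tibble from [genomic_bins()].
#' @return Numeric vector of per-bin mean scores.
#' @export
compute_signal_track <- function(bedgraph, bins) {
  iv <- read_bed_intervals(bedgraph, n_fields = 4)
  if (nrow(iv) > 0) {
    iv$score <- suppressWarnings(as.numeric(iv$extra))
    bad <- which(is.na(iv$score))
    if (length(bad)) {
      abort(sprintf("non-numeric bedGraph score at line %d", iv$.line[bad[1]]))
    }
    for (ch in unique(iv$chrom)) {
      sub <- arrange(filter(iv, .data$chrom == ch), .data$start)
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
        abort(sprintf("overlapping bedGraph intervals on %s (ambiguous signal)", ch))
      }
    }
  }
  out <- numeric(nrow(bins))
  if (nrow(iv) == 0) return(out)
  bg <- bins_to_granges(bins)
  gr <- intervals_to_granges(iv)
  hits <- GenomicRanges::findOverlaps(bg, gr)
  if (length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov_start <- pmax(bins$start[qi], iv$start[si])
    ov_end <- pmin(bins$end[qi], iv$end[si])
    contrib <- (ov_end - ov_start) * iv$score[si]
    agg <- tapply(contrib, qi, sum)
    out[as.integer(names(agg))] <- agg / (bins$end - bins$start)[as.integer(names(agg))]
  }
  out
}

#' Assemble per-pair observations and the pair lattice
#'
#' Combines dense pair counts with per-bin covariate tracks: genomic
#' distance is the bp distance between bin midpoints (`pseudocount *
#' bin_size` on the diagonal); GC, TE and accessibility are the arithmetic
#' means of the two bins' values, floored at `pseudocount` so that all logs
#' in the bias regression are defined.
#'
#' @param pairs Tibble of 0-based `i`, `j`, `y` (dense; see
#'   [read_contact_matrix()]).
#' @param gc,te,acc Per-bin tracks aligned with `bins`.
#' @param bins Bin tibble from [genomic_bins()].
#' @param pseudocount Positive smoothing constant (default 0.5).
#' @return A list of class `hic_dataset` with `observations` (tibble
#'   `site`, `i`, `j` as 1-based lattice coordinates, `bin_i`, `bin_j`, `y`,
#'   `D`, `GC`, `TE`, `ACC`) and `lattice` over the region's upper triangle.
#' @export
assemble_observations <- function(pairs, gc, te, acc, bins,
                                  pseudocount = 0.5) {
  m <- nrow(bins)
  if (length(gc) != m || length(te) != m || length(acc) != m) {
    abort("track length does not match the number of bins")
  }
  if (any(pairs$i >= m | pairs$j >= m | pairs$i < 0 | pairs$j < 0)) {
    abort("pair index outside the bin set")
  }
  if (pseudocount <= 0) abort("`pseudocount` must be positive")
  bin_size <- max(bins$end - bins$start)
  mid <- (bins$start + bins$end) / 2
  ii <- pairs$i + 1L
  jj <- pairs$j + 1L
  D <- abs(mid[jj] - mid[ii])
  D[pairs$i == pairs$j] <- pseudocount * bin_size
  obs <- tibble(
    site = seq_len(nrow(pairs)),
    i = ii, j = jj, bin_i = pairs$i, bin_j = pairs$j,
    y = as.integer(pairs$y),
    D = D,
    GC = pmax((gc[ii] + gc[jj]) / 2, pseudocount),
    TE = pmax((te[ii] + te[jj]) / 2, pseudocount),
    ACC = pmax((acc[ii] + acc[jj]) / 2, pseudocount)
  )
  lat <- pair_lattice(sites = obs[, c("i", "j")])
  structure(list(observations = obs, lattice = lat, bins = bins,
                 pseudocount = pseudocount),
            class = "hic_dataset")
}

#' Write interaction calls as BEDPE
#'
#' Standard ten BEDPE columns plus per-component posterior probabilities and
#' the role label. The score column is the posterior probability of the
#' true-signal component scaled to 0..1000.
#'
#' @param calls Call tibble from [call_interactions()] (needs `bin_i`,
#'   `bin_j` columns or `i`, `j` interpretable against `bins`).
#' @param bins Bin tibble from [genomic_bins()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls_bedpe <- function(calls, bins, path) {
  prob_cols <- grep("^p_", names(calls), value = TRUE)
  bi <- if ("bin_i" %in% names(calls)) calls$bin_i else calls$i - 1L
  bj <- if ("bin_j" %in% names(calls)) calls$bin_j else calls$j - 1L
  if (length(bi) > 0 && (max(bi, bj) >= nrow(bins) || min(bi, bj) < 0)) {
    abort("calls refer to unknown bins")
  }
  df <- tibble(
    chrom1 = bins$chrom[bi + 1L], start1 = bins$start[bi + 1L],
    end1 = bins$end[bi + 1L],
    chrom2 = bins$chrom[bj + 1L], start2 = bins$start[bj + 1L],
    end2 = bins$end[bj + 1L],
    name = sprintf("pair_%d_%d", bi, bj),
    score = round(1000 * calls$p_signal),
    strand1 = ".", strand2 = "."
  )
  for (p in prob_cols) df[[p]] <- round(calls[[p]], 6)
  df$label <- calls$label
  header <- c(
    "# hicmrf BEDPE v1",
    paste0("#", paste(names(df), collapse = "\t"))
  )
  writeLines(header, path)
  if (nrow(df) > 0) {
    readr::write_tsv(df, path, col_names = FALSE, progress = FALSE,
                     append = TRUE)
  }
  invisible(path)
}

#' Read a BEDPE call file written by [write_calls_bedpe()]
#'
#' @param path BEDPE path.
#' @param bins Bin tibble used when writing.
#' @return Call tibble with bin indices, probabilities and labels.
#' @export
read_calls_bedpe <- function(path, bins) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  cols <- strsplit(sub("^#", "", hdr[length(hdr)]), "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    out <- as_tibble(setNames(rep(list(character()), length(cols)), cols))
    return(out)
  }
  df <- readr::read_tsv(I(body), col_names = cols, show_col_types = FALSE,
                        progress = FALSE)
  bin_size <- max(bins$end - bins$start)
  mutate(df,
         bin_i = as.integer(.data$start1 %/% bin_size),
         bin_j = as.integer(.data$start2 %/% bin_size))
}
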