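#' Read a genome as a set of replicons
#'
#' Loads replicon sequences from a FASTA file and CDS annotations from
#' either a GFF3 file (1-based inclusive coordinates, converted at this
#' boundary) or a tab-separated CDS table that is already in the package's
#' internal convention. All coordinates inside the package are 0-based
#' half-open; minus-strand CDS sequences are extracted by
#' reverse-complementation.
#'
#' A CDS TSV must contain the columns `gene_id`, `replicon_id`, `start`,
#' `end` (0-based half-open), `strand` (`+`/`-`) and `phase` (0, 1 or 2).
#'
#' @param fasta_path Path to a FASTA file of replicon sequences. FASTA ids
#'   (first whitespace-delimited token) must match the annotation's
#'   replicon ids.
#' @param annotation_path Path to a GFF3 (`.gff`/`.gff3`) or CDS TSV file.
#' @param roles Optional named character vector mapping replicon ids to a
#'   declared role (`"chromosome"`, `"chromid"`, `"plasmid"`,
#'   `"unknown"`). At most one replicon may be declared chromosome.
#' @return A `replicon_set`: a list with elements `sequences`
#'   (a [Biostrings::DNAStringSet]), `cds` (a tibble of CDS records) and
#'   `replicons` (a tibble with `replicon_id`, `length_bp`,
#'   `declared_role`).
#' @export
read_genome <- function(fasta_path, annotation_path, roles = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  cds <- if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    read_gff3_cds(annotation_path)
  } else {
    read_cds_tsv(annotation_path)
  }
  replicon_set(seqs, cds, roles)
}

#' Construct a replicon set from in-memory components
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) of replicon sequences.
#' @param cds A tibble of CDS records with 0-based half-open coordinates
#'   (`gene_id`, `replicon_id`, `start`, `end`, `strand`, `phase`).
#' @param roles Optional named character vector of declared roles.
#' @return A `replicon_set` object.
#' @export
replicon_set <- function(sequences, cds, roles = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  cds <- as_tibble(cds)
  check_columns(cds, c("gene_id", "replicon_id", "start", "end", "strand", "phase"),
                "CDS table")
  unknown <- setdiff(unique(cds$replicon_id), names(sequences))
  if (length(unknown) > 0) {
    stop_ecr("annotation references replicon(s) absent from the FASTA: ",
             paste(unknown, collapse = ", "))
  }
  if (any(cds$end <= cds$start)) {
    stop_ecr("CDS with end <= start: ",
             paste(cds$gene_id[cds$end <= cds$start], collapse = ", "))
  }
  lens <- setNames(Biostrings::width(sequences), names(sequences))
  bad <- cds$start < 0 | cds$end > lens[cds$replicon_id]
  if (any(bad)) {
    stop_ecr("CDS outside replicon bounds: ",
             paste(cds$gene_id[bad], collapse = ", "))
  }
  if (!all(cds$strand %in% c("+", "-"))) stop_ecr("CDS strand must be '+' or '-'")
  if (!all(cds$phase %in% 0:2)) stop_ecr("CDS phase must be 0, 1 or 2")

  role <- setNames(rep("unknown", length(sequences)), names(sequences))
  if (!is.null(roles)) {
    unknown_role_ids <- setdiff(names(roles), names(sequences))
    if (length(unknown_role_ids) > 0) {
      stop_ecr("roles given for unknown replicon(s): ",
               paste(unknown_role_ids, collapse = ", "))
    }
    stopifnot(all(roles %in% c("chromosome", "chromid", "plasmid", "unknown")))
    role[names(roles)] <- roles
    if (sum(role == "chromosome") > 1) {
      stop_ecr("at most one replicon may be declared chromosome")
    }
  }
  structure(
    list(
      sequences = sequences,
      cds = arrange(cds, .data$replicon_id, .data$start),
      replicons = tibble(
        replicon_id = names(sequences),
        length_bp = unname(lens),
        declared_role = unname(role)
      )
    ),
    class = "replicon_set"
  )
}

#' @export
print.replicon_set <- function(x, ...) {
  cat(sprintf("<replicon_set> %d replicon(s), %d CDS\n",
              nrow(x$replicons), nrow(x$cds)))
  print(x$replicons)
  invisible(x)
}

# GFF3 CDS features via rtracklayer; coordinates converted 1-based
# inclusive -> 0-based half-open at this boundary.
read_gff3_cds <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_ecr("reading GFF3 requires the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(path))
  gr <- gr[gr$type == "CDS", , drop = FALSE]
  ids <- if ("ID" %in% names(gr)) as.character(gr$ID) else rep(NA_character_, nrow(gr))
  if ("locus_tag" %in% names(gr)) {
    ids <- ifelse(is.na(ids), as.character(gr$locus_tag), ids)
  }
  ids[is.na(ids)] <- paste0("cds_", seq_len(sum(is.na(ids))))
  phase <- if ("phase" %in% names(gr)) as.integer(gr$phase) else rep(0L, nrow(gr))
  phase[is.na(phase)] <- 0L
  tibble(
    gene_id = ids,
    replicon_id = as.character(gr$seqnames),
    start = as.integer(gr$start) - 1L,
    end = as.integer(gr$end),
    strand = as.character(gr$strand),
    phase = phase
  )
}

read_cds_tsv <- function(path) {
  cds <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(cds, c("gene_id", "replicon_id", "start", "end", "strand", "phase"),
                "CDS TSV")
  mutate(cds, start = as.integer(.data$start), end = as.integer(.data$end),
         phase = as.integer(.data$phase))
}

#' Write a CDS table
#'
#' Writes the package's CDS table (0-based half-open) as TSV;
#' `read_genome()` on the written file reproduces the input.
#'
#' @param cds A CDS tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_tsv <- function(cds, path) {
  readr::write_tsv(cds, path, progress = FALSE)
  invisible(path)
}

#' Extract CDS nucleotide sequences
#'
#' Returns the coding sequence of every CDS of a replicon set, with
#' minus-strand features reverse-complemented and the `phase` offset
#' trimmed from the 5' end.
#'
#' @param genome A `replicon_set`.
#' @return A named [Biostrings::DNAStringSet], one element per CDS.
#' @export
cds_sequences <- function(genome) {
  stopifnot(inherits(genome, "replicon_set"))
  out <- vapply(seq_len(nrow(genome$cds)), function(i) {
    row <- genome$cds[i, ]
    s <- as.character(Biostrings::subseq(genome$sequences[[row$replicon_id]],
                                         start = row$start + 1L, end = row$end))
    if (row$strand == "-") s <- revcomp(s)
    if (row$phase > 0) s <- substr(s, row$phase + 1L, nchar(s))
    s
  }, character(1))
  Biostrings::DNAStringSet(setNames(out, genome$cds$gene_id))
}

#' Read a read-depth table
#'
#' Accepts either per-base depth in `samtools depth` layout (columns
#' `replicon`, `pos` 1-based, `depth`) or a pre-windowed table (columns
#' `replicon_id`, `window_start`, `window_end`, `depth`), which passes
#' through unchanged. Per-base input is aggregated to mean depth per
#' fixed-width window; a trailing partial window is kept when it spans at
#' least half of `window_bp`.
#'
#' @param path Path to a TSV file (a header is expected for the windowed
#'   layout; the per-base layout may be headerless like `samtools depth`).
#' @param window_bp Window width in bp for aggregating per-base depth.
#' @return A tibble with columns `replicon_id`, `window_start`,
#'   `window_end` (0-based half-open) and `depth` (mean reads per base).
#' @export
read_depth_table <- function(path, window_bp = 1000L) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warn("empty depth file; returning an empty table")
    return(tibble(replicon_id = character(), window_start = integer(),
                  window_end = integer(), depth = double()))
  }
  has_header <- grepl("replicon|window|pos|depth", first, ignore.case = TRUE)
  raw <- readr::read_tsv(path, col_names = has_header == TRUE,
                         show_col_types = FALSE, progress = FALSE)
  if (!has_header) {
    if (ncol(raw) != 3L) stop_ecr("headerless depth file must have 3 columns")
    names(raw) <- c("replicon", "pos", "depth")
  }
  if (all(c("replicon_id", "window_start", "window_end", "depth") %in% names(raw))) {
    out <- select(raw, "replicon_id", "window_start", "window_end", "depth")
    if (any(out$depth < 0)) stop_ecr("negative depth values")
    return(as_tibble(out))
  }
  check_columns(raw, c("replicon", "pos", "depth"), "per-base depth TSV")
  if (any(raw$depth < 0)) stop_ecr("negative depth values")
  window_depth(rename(raw, replicon_id = "replicon"), window_bp)
}

# Aggregate a per-base (replicon_id, pos 1-based, depth) table to windows.
# Per replicon: sort (with a warning if needed), window, bind.
window_depth <- function(per_base, window_bp) {
  pieces <- dplyr::group_split(group_by(per_base, .data$replicon_id))
  out <- map(pieces, function(g) {
    if (is.unsorted(g$pos)) {
      warn(sprintf("unsorted positions for replicon '%s'; sorting",
                   g$replicon_id[1]))
      g <- arrange(g, .data$pos)
    }
    idx <- (g$pos - 1L) %/% window_bp
    agg <- g |>
      mutate(win = idx) |>
      group_by(.data$win) |>
      summarise(replicon_id = first(.data$replicon_id),
                depth = mean(.data$depth),
                last_pos = max(.data$pos), .groups = "drop") |>
      mutate(window_start = .data$win * window_bp,
             window_end = .data$window_start + window_bp)
    # trailing partial window: end at last observed base; drop if < half a
    # window wide
    last <- which.max(agg$win)
    span <- agg$last_pos[last] - agg$window_start[last]
    if (span < window_bp) {
      if (span >= window_bp / 2) {
        agg$window_end[last] <- agg$window_start[last] + span
      } else {
        agg <- agg[-last, ]
      }
    }
    select(agg, "replicon_id", "window_start", "window_end", "depth")
  })
  bind_rows(out)
}

#' Write a windowed depth table
#'
#' @param depth A windowed depth tibble as returned by
#'   [read_depth_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depth, path) {
  check_columns(depth, c("replicon_id", "window_start", "window_end", "depth"),
                "depth table")
  readr::write_tsv(depth, path, progress = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene_id`, `replicon_id`, `log2fc`,
#'   `pvalue` (one row per gene).
#' @param strain,reference Optional labels stored as attributes.
#' @return A tibble with attributes `strain` and `reference`.
#' @export
read_de_table <- function(path, strain = NULL, reference = NULL) {
  de <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(de, c("gene_id", "replicon_id", "log2fc", "pvalue"), "DE table")
  if (anyDuplicated(de$gene_id)) {
    stop_ecr("duplicated gene_id in DE table: ",
             paste(unique(de$gene_id[duplicated(de$gene_id)]), collapse = ", "))
  }
  if (any(de$pvalue < 0 | de$pvalue > 1, na.rm = TRUE)) {
    stop_ecr("p-values outside [0, 1] in DE table")
  }
  attr(de, "strain") <- strain
  attr(de, "reference") <- reference
  de
}

#' Write a differential-expression table
#'
#' @param de A DE tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  check_columns(de, c("gene_id", "replicon_id", "log2fc", "pvalue"), "DE table")
  readr::write_tsv(de, path, progress = FALSE)
  invisible(path)
}

#' Write / read trees in newick format
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()] so that
#' every tree produced by the package round-trips with leaf labels
#' preserved.
#'
#' @param tree An [ape::phylo] object.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
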