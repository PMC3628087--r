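#' Mutation catalogs and genome models
#'
#' A mutation catalog is a data frame of per-clone somatic substitutions with
#' columns `clone`, `chrom`, `pos` (1-based), `ref` and `alt`, kept in
#' canonical (clone, chrom, pos) order with no duplicate sites. A genome model
#' holds the ordered chromosome names and lengths, optionally with the full
#' sequence, and acts as the coordinate authority for every downstream stage.
#'
#' @name catalog
NULL

BASES <- c("A", "C", "G", "T")

complement_base <- function(b) chartr("ACGT", "TGCA", b)

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a validated mutation catalog
#'
#' Validates, canonically sorts and classes a table of substitutions.
#' Coordinates are 1-based, fully closed, on the forward reference strand.
#' Adjacent substitutions at consecutive positions within a clone are kept as
#' separate records and flagged in the `coalesced` column.
#'
#' @param df data frame with columns `clone`, `chrom`, `pos`, `ref`, `alt`.
#' @param genome optional [genome_model()]; when given, chromosome names must
#'   exist in the genome (unknown chromosomes are an error, not a warning),
#'   positions must not exceed chromosome lengths, and when sequence is
#'   present each `ref` must match the genome base.
#' @param provenance free-text source tag stored as an attribute.
#' @return a `mutation_catalog` data frame sorted by (clone, chrom, pos) with
#'   a logical `coalesced` column.
#' @export
mutation_catalog <- function(df, genome = NULL, provenance = "user") {
  req <- c("clone", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$clone <- as.character(df$clone)
  df$chrom <- as.character(df$chrom)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))

  n <- nrow(df)
  if (n == 0L) {
    df$pos <- integer(0)
    df$coalesced <- logical(0)
    return(structure(df, class = c("mutation_catalog", "data.frame"),
                     provenance = provenance, genome = genome))
  }

  pos_num <- suppressWarnings(as.numeric(df$pos))
  bad_pos <- is.na(pos_num) | pos_num != round(pos_num) | pos_num < 1
  bad_ref <- !(df$ref %in% BASES)
  bad_alt <- !(df$alt %in% BASES)
  bad_same <- !bad_ref & !bad_alt & df$ref == df$alt
  if (any(bad_pos | bad_ref | bad_alt | bad_same)) {
    msgs <- c(
      sprintf("line %d: invalid pos '%s'", which(bad_pos), df$pos[bad_pos]),
      sprintf("line %d: invalid ref base '%s'", which(bad_ref),
              df$ref[bad_ref]),
      sprintf("line %d: invalid alt base '%s'", which(bad_alt),
              df$alt[bad_alt]),
      sprintf("line %d: ref equals alt", which(bad_same)))
    stop("invalid mutation record(s):\n", paste(msgs, collapse = "\n"))
  }
  df$pos <- as.integer(pos_num)

  chrom_levels <- sort(unique(df$chrom))
  if (!is.null(genome)) {
    unknown <- setdiff(df$chrom, genome$chroms$name)
    if (length(unknown)) {
      stop("chromosome(s) absent from genome model: ",
           paste(unknown, collapse = ", "))
    }
    chrom_levels <- genome$chroms$name
    len <- genome$chroms$length[match(df$chrom, genome$chroms$name)]
    over <- which(df$pos > len)
    if (length(over)) {
      stop("position(s) beyond chromosome length at line(s): ",
           paste(over, collapse = ", "))
    }
    if (!is.null(genome$sequence)) {
      gbase <- genome_base(genome, df$chrom, df$pos)
      mism <- which(gbase != df$ref)
      if (length(mism)) {
        stop("ref base disagrees with genome sequence at line(s): ",
             paste(mism, collapse = ", "))
      }
    }
  }

  key <- paste(df$clone, df$chrom, df$pos, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (clone, chrom, pos) site(s) at line(s): ",
         paste(dup, collapse = ", "))
  }

  ord <- order(df$clone, match(df$chrom, chrom_levels), df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  same_group <- df$clone[-1] == df$clone[-n] & df$chrom[-1] == df$chrom[-n]
  adj <- n > 1 & c(FALSE, same_group & diff(df$pos) == 1L)
  df$coalesced <- adj | c(adj[-1], FALSE)

  structure(df, class = c("mutation_catalog", "data.frame"),
            provenance = provenance, genome = genome,
            chrom_levels = chrom_levels)
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("mutation catalog:", nrow(x), "substitutions,",
      length(unique(x$clone)), "clone(s),",
      length(unique(x$chrom)), "chromosome(s)\n")
  cat("provenance:", attr(x, "provenance"), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

clone_ids <- function(catalog) unique(catalog$clone)

#' Read a mutation table
#'
#' Reads a per-clone substitution catalog from the native tab-separated
#' dialect (header `clone  chrom  pos  ref  alt`) or from a VCF file. VCF
#' sample columns map to clone ids (a record is assigned to every sample
#' whose genotype carries the alternate allele); multi-allelic VCF records
#' are rejected. Malformed rows are reported with their line numbers and
#' nothing is silently dropped.
#'
#' @param path input file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param genome optional [genome_model()] used for validation.
#' @return a [mutation_catalog()].
#' @export
read_mutation_table <- function(path, dialect = c("tsv", "vcf"),
                                genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE)
    cat_try <- tryCatch(
      mutation_catalog(df, genome = genome, provenance = path),
      error = function(e) e)
    if (inherits(cat_try, "error")) {
      # validator line numbers are row indices; shift by one for the header
      msg <- conditionMessage(cat_try)
      m <- gregexpr("(?<=line )\\d+", msg, perl = TRUE)
      regmatches(msg, m) <- lapply(regmatches(msg, m),
                                   function(v) as.integer(v) + 1L)
      stop("while parsing ", path, ": ", msg, call. = FALSE)
    }
    return(cat_try)
  }
  read_vcf_catalog(path, genome = genome)
}

read_vcf_catalog <- function(path, genome = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF import requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multi-allelic VCF records are not supported (line(s): ",
         paste(which(grepl(",", alt, fixed = TRUE)), collapse = ", "), ")")
  }
  gt <- tryCatch(vcfR::extract.gt(v), error = function(e) NULL)
  rows <- list()
  if (is.null(gt) || ncol(gt) == 0L) {
    rows[[1]] <- data.frame(clone = basename(path), chrom = fix[, "CHROM"],
                            pos = fix[, "POS"], ref = fix[, "REF"], alt = alt,
                            stringsAsFactors = FALSE)
  } else {
    for (sm in colnames(gt)) {
      carries <- !is.na(gt[, sm]) & grepl("1", gt[, sm])
      if (any(carries)) {
        rows[[sm]] <- data.frame(clone = sm, chrom = fix[carries, "CHROM"],
                                 pos = fix[carries, "POS"],
                                 ref = fix[carries, "REF"],
                                 alt = alt[carries], stringsAsFactors = FALSE)
      }
    }
  }
  mutation_catalog(do.call(rbind, rows), genome = genome, provenance = path)
}

#' Write a mutation catalog in the native TSV dialect
#'
#' @param catalog a [mutation_catalog()].
#' @param path output file.
#' @export
write_mutation_table <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog)[c("clone", "chrom", "pos",
                                              "ref", "alt")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genome model
#'
#' @param chroms data frame with columns `name` and `length` (bp), in
#'   genome order.
#' @param sequence optional named character vector of chromosome sequences;
#'   lengths must agree with `chroms$length`.
#' @return a `genome_model` list with elements `chroms`, `sequence`,
#'   `total_length`.
#' @export
genome_model <- function(chroms, sequence = NULL) {
  chroms <- as.data.frame(chroms)
  if (!all(c("name", "length") %in% names(chroms))) {
    stop("chroms needs 'name' and 'length' columns")
  }
  chroms$name <- as.character(chroms$name)
  chroms$length <- as.numeric(chroms$length)
  if (nrow(chroms) == 0L) stop("genome model needs at least one chromosome")
  if (anyDuplicated(chroms$name)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(chroms$name[duplicated(chroms$name)]), collapse = ", "))
  }
  if (any(!is.finite(chroms$length) | chroms$length < 1)) {
    stop("chromosome lengths must be positive")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (!all(chroms$name %in% names(sequence))) {
      stop("sequence missing for chromosome(s): ",
           paste(setdiff(chroms$name, names(sequence)), collapse = ", "))
    }
    sequence <- sequence[chroms$name]
    if (!all(nchar(sequence) == chroms$length)) {
      stop("sequence length disagrees with declared chromosome length")
    }
  }
  structure(list(chroms = chroms, sequence = sequence,
                 total_length = sum(chroms$length)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome model:", nrow(x$chroms), "chromosome(s),",
      format(x$total_length, big.mark = ","), "bp total,",
      if (is.null(x$sequence)) "lengths only" else "with sequence", "\n")
  invisible(x)
}

#' Read a genome from FASTA or a chromosome-length table
#'
#' A file whose first non-blank character is `>` is parsed as FASTA (sequence
#' attached); otherwise it is read as a two-column `name<TAB>length` table
#' (lengths only).
#'
#' @param path FASTA file or length table.
#' @return a [genome_model()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty genome file: ", path)
  if (startsWith(trimws(first), ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    nms <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(nms)) {
      stop("duplicate chromosome name(s) in FASTA: ",
           paste(unique(nms[duplicated(nms)]), collapse = ", "))
    }
    sequence <- stats::setNames(as.character(seqs), nms)
    return(genome_model(data.frame(name = nms, length = nchar(sequence)),
                        sequence = sequence))
  }
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("name", "length"),
                           colClasses = c("character", "numeric"))
  genome_model(tab)
}

#' Write a genome model with sequence as FASTA
#'
#' @param genome a [genome_model()] carrying sequence.
#' @param path output FASTA file.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) stop("genome model carries no sequence")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$sequence), path)
  invisible(path)
}

genome_base <- function(genome, chrom, pos) {
  if (is.null(genome$sequence)) stop("genome model carries no sequence")
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    out[idx] <- substring(genome$sequence[[ch]], pos[idx], pos[idx])
  }
  out
}

#' Export the per-mutation rainfall table
#'
#' One row per mutation in genome order per clone, with the intermutational
#' distance to the next downstream mutation on the same chromosome (`NA` for
#' the most downstream mutation of a chromosome) and the id of the cluster
#' the mutation belongs to, if any. Suitable for rainfall plotting with a
#' log-scaled IMD axis.
#'
#' @param catalog a [mutation_catalog()].
#' @param imds the [compute_imds()] result for `catalog`.
#' @param path output TSV file.
#' @param clusters optional [call_clusters()] result; fills `cluster_id`.
#' @export
write_rainfall_table <- function(catalog, imds, path, clusters = NULL) {
  if (!is.null(imds$n_total) && imds$n_total != nrow(catalog)) {
    stop("IMD series was not computed from this catalog (size mismatch)")
  }
  df <- as.data.frame(catalog)[c("clone", "chrom", "pos", "ref", "alt")]
  df$imd <- rep(NA_integer_, nrow(df))
  if (nrow(df) > 1) {
    same <- df$clone[-1] == df$clone[-nrow(df)] &
      df$chrom[-1] == df$chrom[-nrow(df)]
    df$imd[c(same, FALSE)] <- diff(df$pos)[same]
  }
  df$cluster_id <- rep(NA_character_, nrow(df))
  if (!is.null(clusters) && nrow(clusters)) {
    for (k in seq_len(nrow(clusters))) {
      df$cluster_id[clusters$members[[k]]] <- clusters$cluster_id[k]
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export cluster calls as a BED-like table
#'
#' Columns are `chrom`, 0-based half-open `start0`, `end`,
#' `clone:cluster_id`, `n_mutations` and `polarity` (BED convention,
#' converted from the internal 1-based closed coordinates).
#'
#' @param clusters a [call_clusters()] result.
#' @param path output TSV file.
#' @export
write_cluster_bed <- function(clusters, path) {
  df <- data.frame(chrom = clusters$chrom,
                   start0 = clusters$start - 1L,
                   end = clusters$end,
                   name = paste0(clusters$clone, ":", clusters$cluster_id),
                   n_mutations = clusters$n_mutations,
                   polarity = clusters$polarity)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
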