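#' Read a gene annotation catalog
#'
#' Reads gene loci plus category tags into a [GenomicRanges::GRanges] with
#' metadata columns `gene_id`, `symbol`, `categories` (a `CharacterList` of
#' tags such as `RBP`, `miRNA`, `TF`, `kinase`) and `family` (e.g. a
#' replication-dependent histone family label, or `NA`).
#'
#' Two dialects are supported. `"bed"` is standard BED (0-based half-open,
#' whitespace-separated: chrom, start, end, name, score, strand); the name
#' column becomes `gene_id`. `"tsv"` is the package's richer tab-separated
#' dialect with a header line
#' `gene_id symbol chrom start end strand categories family`, 1-based
#' inclusive coordinates (as in GFF) and comma-separated category tags.
#' Both are converted at this boundary to the internal convention
#' (GRanges, 1-based closed); coordinates never change convention again
#' downstream.
#'
#' @param path path to the annotation file.
#' @param dialect `"tsv"` (default) or `"bed"`.
#' @return `GRanges`, sorted by position, one range per gene.
#' @export
readAnnotation <- function(path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 4))
      stop("malformed BED row at line ", which(nf < 4)[1],
           ": fewer than 4 fields")
    m <- t(vapply(fields, function(f) f[1:6], character(6)))
    start0 <- suppressWarnings(as.numeric(m[, 2]))
    end0 <- suppressWarnings(as.numeric(m[, 3]))
    bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0)
    if (length(bad))
      stop("malformed BED row at line ", bad[1], ": bad coordinates")
    gr <- GenomicRanges::GRanges(
      m[, 1],
      # BED is 0-based half-open; internal is 1-based closed
      IRanges::IRanges(start = start0 + 1, end = end0),
      strand = ifelse(is.na(m[, 6]) | !m[, 6] %in% c("+", "-"), "*", m[, 6]))
    gr$gene_id <- m[, 4]
    gr$symbol <- m[, 4]
    gr$categories <- IRanges::CharacterList(rep(list(character(0)),
                                                length(gr)))
    gr$family <- NA_character_
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
    if (!all(need %in% names(tab)))
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    bad <- which(!is.finite(tab$start) | !is.finite(tab$end) |
                   tab$start > tab$end | tab$start < 1)
    if (length(bad))
      stop("malformed annotation row at line ", bad[1] + 1L,
           ": invalid coordinates")
    gr <- GenomicRanges::GRanges(
      tab$chrom, IRanges::IRanges(tab$start, tab$end),
      strand = ifelse(tab$strand %in% c("+", "-"), tab$strand, "*"))
    gr$gene_id <- tab$gene_id
    gr$symbol <- tab$symbol
    cats <- if ("categories" %in% names(tab)) tab$categories else ""
    cats[is.na(cats)] <- ""
    gr$categories <- IRanges::CharacterList(
      lapply(strsplit(cats, ","), function(x) x[nzchar(x)]))
    gr$family <- if ("family" %in% names(tab)) {
      fam <- tab$family
      fam[!is.na(fam) & fam == ""] <- NA_character_
      fam
    } else NA_character_
  }
  dup <- gr$gene_id[duplicated(gr$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in annotation: ", dup[1])
  names(gr) <- gr$gene_id
  sort(gr, ignore.strand = TRUE)
}

#' Write a gene annotation catalog (TSV dialect)
#'
#' Inverse of [readAnnotation()] for the `"tsv"` dialect (1-based inclusive
#' coordinates, comma-separated categories).
#'
#' @param annotation `GRanges` as produced by [readAnnotation()] or
#'   [simulateAnnotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  tab <- data.frame(
    gene_id = annotation$gene_id,
    symbol = annotation$symbol,
    chrom = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation),
    end = GenomicRanges::end(annotation),
    strand = as.character(GenomicRanges::strand(annotation)),
    categories = vapply(annotation$categories, paste, "", collapse = ","),
    family = annotation$family,
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a log2 expression matrix
#'
#' TSV with a header row of sample ids and gene ids in the first column.
#' Missing values are carried as `NA` and excluded pairwise downstream.
#' A non-numeric body cell is an error naming its coordinates; ragged rows
#' are parse errors.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1]])
  bad <- which(lengths(fields) != ncols)
  if (length(bad))
    stop("ragged row at line ", bad[1], ": expected ", ncols, " fields")
  samples <- fields[[1]][-1]
  genes <- vapply(fields[-1], `[`, "", 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene id in matrix: ", genes[duplicated(genes)][1])
  body <- vapply(fields[-1], function(f) f[-1], character(ncols - 1L))
  body <- if (is.null(dim(body))) matrix(body, ncol = 1L) else t(body)
  num <- suppressWarnings(array(as.numeric(body), dim(body)))
  miss <- body %in% c("", "NA", "na", "NaN")
  bad <- which(is.na(num) & !miss, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at gene '", genes[bad[1, 1]], "', sample '",
         samples[bad[1, 2]], "': ", body[bad[1, , drop = FALSE]])
  dimnames(num) <- list(genes, samples)
  num
}

#' @rdname readExpressionMatrix
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param id_column header label for the gene-id column.
#' @export
writeExpressionMatrix <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write segmented copy-number profiles (SEG)
#'
#' The SEG dialect used by genome browsers/portals: tab-separated columns
#' `Sample, Chromosome, Start, End, Num_Probes, Segment_Mean` and an
#' optional `Call` column. SEG coordinates are 1-based inclusive and pass
#' through unchanged into the internal `GRanges` representation; segments
#' must be non-overlapping within a sample.
#'
#' @param path file path.
#' @return `GRanges` with metadata columns `sample`, `seg_mean`,
#'   `n_probes` and (if present) `call`.
#' @export
readSeg <- function(path) {
  if (!file.exists(path)) stop("SEG file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  if (!all(need %in% names(tab)))
    stop("SEG file must have columns: ", paste(need, collapse = ", "))
  gr <- GenomicRanges::GRanges(tab$Chromosome,
                               IRanges::IRanges(tab$Start, tab$End))
  gr$sample <- tab$Sample
  gr$seg_mean <- tab$Segment_Mean
  gr$n_probes <- if ("Num_Probes" %in% names(tab)) tab$Num_Probes else
    NA_integer_
  if ("Call" %in% names(tab)) gr$call <- tab$Call
  for (s in unique(gr$sample)) {
    g <- gr[gr$sample == s]
    hits <- GenomicRanges::findOverlaps(g, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits)) {
      i <- S4Vectors::queryHits(hits)[1]
      stop("overlapping segments in sample ", s, " near ",
           GenomicRanges::seqnames(g)[i], ":", GenomicRanges::start(g)[i])
    }
  }
  sort(gr, ignore.strand = TRUE)
}

#' @rdname readSeg
#' @param segments `GRanges` with `sample`, `seg_mean`, `n_probes` and
#'   optionally `call` metadata columns.
#' @export
writeSeg <- function(segments, path) {
  tab <- data.frame(
    Sample = segments$sample,
    Chromosome = as.character(GenomicRanges::seqnames(segments)),
    Start = GenomicRanges::start(segments),
    End = GenomicRanges::end(segments),
    Num_Probes = segments$n_probes,
    Segment_Mean = segments$seg_mean,
    stringsAsFactors = FALSE)
  if (!is.null(segments$call)) tab$Call <- segments$call
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column membership table into a named list of gene sets
#'
#' Used for protein-complex catalogs (`complex_id, gene_id`), gene-category
#' tables (`category, gene_id`) and family maps (`gene_id, family`; pass
#' `key = 2`).
#'
#' @param path TSV path with a header row.
#' @param key which column holds the set label (1 or 2).
#' @param min_size drop sets smaller than this (complex catalogs require 2).
#' @return named list of character vectors of gene ids.
#' @export
readMembershipTable <- function(path, key = 1L, min_size = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("membership table needs two columns: ", path)
  sets <- split(tab[[if (key == 1L) 2L else 1L]], tab[[key]])
  sets <- lapply(sets, unique)
  sets[lengths(sets) >= min_size]
}

#' Read a pan-cancer alteration-frequency table
#'
#' Long TSV with columns `gene_id, tumor_type, gain_freq, loss_freq`
#' (fractions of tumors of that type carrying a gain/loss of the gene).
#'
#' @param path TSV path.
#' @return data.frame with those four columns.
#' @export
readFreqTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tumor_type", "gain_freq", "loss_freq")
  if (!all(need %in% names(tab)))
    stop("frequency table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Read a survival cohort table
#'
#' TSV with columns `patient_id, time, event` followed by one expression
#' column per gene.
#'
#' @param path TSV path.
#' @return list with `time`, `event` (named by patient) and `expr`
#'   (genes x patients matrix).
#' @export
readSurvivalCohort <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(tab)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$time < 0)) stop("negative survival time in ", path)
  expr <- t(as.matrix(tab[, setdiff(names(tab), need), drop = FALSE]))
  colnames(expr) <- tab$patient_id
  list(time = stats::setNames(tab$time, tab$patient_id),
       event = stats::setNames(as.integer(tab$event), tab$patient_id),
       expr = expr)
}

#' Read / write a run configuration (YAML)
#'
#' A single declarative file holding every tunable and seed of the pipeline;
#' serializing then reloading yields an identical configuration. Unknown
#' keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML path.
#' @param defaults a complete default configuration (see [simConfig()]).
#' @return configuration list with defaults filled in.
#' @export
readConfig <- function(path, defaults = simConfig()) {
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, user)
  # YAML maps come back as named lists; restore the atomic-vector shape
  # the defaults use (names survive through unlist)
  for (k in names(merged))
    if (is.atomic(defaults[[k]]) && is.list(merged[[k]]))
      merged[[k]] <- unlist(merged[[k]])
  class(merged) <- class(defaults)
  merged
}

#' @rdname readConfig
#' @param config configuration list.
#' @export
writeConfig <- function(config, path) {
  # named atomic vectors become YAML maps so their names round-trip
  out <- lapply(unclass(config), function(v)
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(out, path)
  invisible(path)
}
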