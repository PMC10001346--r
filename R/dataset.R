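#' Construct a mutation dataset
#'
#' Bundles somatic point-mutation calls into the container used by all panel
#' design and evaluation functions. Each record is one observed mutation
#' event (one row of the input table); records sharing a genomic site
#' (chromosome, position) are aggregated into a weighted site table, so a
#' recurrently mutated base contributes its full event count to every
#' downstream "number of mutations" unless weights are collapsed at design
#' time.
#'
#' @param chrom character vector of chromosome labels. Labels are opaque:
#'   `"chr1"` and `"1"` are different chromosomes, no normalization is done.
#' @param pos integer vector of 1-based genomic positions (bp).
#' @param sample optional character vector of sample identifiers.
#' @param gene optional character vector of gene labels.
#' @return An object of class `mutation_dataset`: a list with
#'   \describe{
#'     \item{records}{data.frame of the individual mutation events
#'       (`chrom`, `pos`, `sample`, `gene`, `site` index into `sites`).}
#'     \item{sites}{data.frame of distinct mutated sites sorted by
#'       (`chrom`, `pos`), with recurrence `weight` (number of records at
#'       the site) and a representative `gene` label.}
#'     \item{samples}{character vector of distinct sample ids present.}
#'   }
#' @examples
#' ds <- mutation_dataset(chrom = c("chr1", "chr1", "chr1", "chr2"),
#'                        pos   = c(100, 100, 250, 40),
#'                        sample = c("s1", "s2", "s1", "s2"))
#' ds$sites
#' @export
mutation_dataset <- function(chrom, pos, sample = NULL, gene = NULL) {
  chrom <- as.character(chrom)
  if (length(chrom) != length(pos)) {
    stop("`chrom` and `pos` must have equal length")
  }
  pos_num <- suppressWarnings(as.numeric(pos))
  bad <- which(is.na(chrom) | !nzchar(chrom) | is.na(pos_num) |
                 pos_num < 1 | pos_num != floor(pos_num))
  if (length(bad)) {
    stop("invalid mutation rows (need non-empty chrom, integer position >= 1): rows ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" ... (%d total)", length(bad)) else "")
  }
  pos <- as.integer(pos_num)
  n <- length(pos)
  sample <- if (is.null(sample)) rep(NA_character_, n) else as.character(sample)
  gene <- if (is.null(gene)) rep(NA_character_, n) else as.character(gene)

  ord <- order(chrom, pos)
  records <- data.frame(chrom = chrom, pos = pos, sample = sample, gene = gene,
                        stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(records) <- NULL

  key <- paste(records$chrom, records$pos, sep = "\r")
  first <- !duplicated(key)
  sites <- data.frame(chrom = records$chrom[first], pos = records$pos[first],
                      weight = as.integer(table(factor(key, levels = key[first]))),
                      gene = records$gene[first], stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  records$site <- match(key, key[first])

  structure(list(records = records, sites = sites,
                 samples = sort(unique(records$sample[!is.na(records$sample)]))),
            class = "mutation_dataset")
}

#' @export
print.mutation_dataset <- function(x, ...) {
  cat(sprintf("Mutation dataset: %d records at %d sites on %d chromosome(s)\n",
              nrow(x$records), nrow(x$sites), length(unique(x$sites$chrom))))
  if (length(x$samples)) {
    cat(sprintf("  %d samples; median records/sample: %s\n", length(x$samples),
                format(stats::median(table(x$records$sample)))))
  }
  invisible(x)
}

#' Read a delimited mutation table
#'
#' Reads a TSV/CSV of somatic mutation calls into a [mutation_dataset()].
#' Only chromosome and position are required; sample and gene columns are
#' used when present for per-sample efficacy evaluation and gene filtering.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator; defaults to `","` for `.csv` files and tab
#'   otherwise.
#' @param chrom_col,pos_col,sample_col,gene_col column names
#'   (defaults `"chrom"`, `"pos"`, `"sample"`, `"gene"`). Sample and gene
#'   columns are optional in the file.
#' @return a [mutation_dataset()].
#' @export
read_mutation_table <- function(path, sep = NULL,
                                chrom_col = "chrom", pos_col = "pos",
                                sample_col = "sample", gene_col = "gene") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  missing_cols <- setdiff(c(chrom_col, pos_col), names(tab))
  if (length(missing_cols)) {
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    return(mutation_dataset(character(0), integer(0)))
  }
  pos_raw <- tab[[pos_col]]
  pos_num <- suppressWarnings(as.numeric(pos_raw))
  bad <- which(is.na(pos_num) | pos_num < 1 | pos_num != floor(pos_num))
  if (length(bad)) {
    stop("non-integer or non-positive position in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" ... (%d total)", length(bad)) else "",
         " (values like ", paste(utils::head(unique(pos_raw[bad]), 3), collapse = ", "), ")")
  }
  mutation_dataset(chrom = tab[[chrom_col]], pos = as.integer(pos_num),
                   sample = if (sample_col %in% names(tab)) tab[[sample_col]],
                   gene = if (gene_col %in% names(tab)) tab[[gene_col]])
}

#' Read mutation positions from a VCF
#'
#' Extracts CHROM/POS from a VCF into a [mutation_dataset()]. Only positions
#' are used by the panel design algorithm; each VCF record line counts once,
#' so multi-allelic sites split across lines count once per line. Requires
#' the `vcfR` package.
#'
#' @param path path to a VCF file.
#' @return a [mutation_dataset()] without sample or gene annotation.
#' @export
read_vcf_positions <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the 'vcfR' package")
  }
  fix <- vcfR::getFIX(vcfR::read.vcfR(path, verbose = FALSE))
  mutation_dataset(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

#' Filter a mutation dataset by gene label
#'
#' @param dataset a [mutation_dataset()].
#' @param genes if non-NULL, keep only records whose gene label is in this set.
#' @param exclude_genes if non-NULL, drop records whose gene label is in this
#'   set.
#' @param require_gene if TRUE, records without a gene label are dropped when
#'   `genes` is given; by default unlabeled records are kept.
#' @return a filtered [mutation_dataset()].
#' @export
filter_genes <- function(dataset, genes = NULL, exclude_genes = NULL,
                         require_gene = FALSE) {
  stopifnot(inherits(dataset, "mutation_dataset"))
  rec <- dataset$records
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(genes)) {
    keep <- keep & (rec$gene %in% genes | (!require_gene & is.na(rec$gene)))
  }
  if (!is.null(exclude_genes)) {
    keep <- keep & !(rec$gene %in% exclude_genes)
  }
  mutation_dataset(rec$chrom[keep], rec$pos[keep], rec$sample[keep], rec$gene[keep])
}

#' Total mutation weight of a dataset
#'
#' @param dataset a [mutation_dataset()].
#' @param collapse_recurrent if TRUE each distinct site counts once
#'   regardless of recurrence.
#' @return total mutation weight (number of events, or sites if collapsed).
#' @export
dataset_weight <- function(dataset, collapse_recurrent = FALSE) {
  if (collapse_recurrent) nrow(dataset$sites) else sum(dataset$sites$weight)
}

# site weights as used by the selectors
site_weights <- function(dataset, collapse_recurrent = FALSE) {
  if (collapse_recurrent) rep(1L, nrow(dataset$sites)) else dataset$sites$weight
}

# per-chromosome site index lookup; sites are sorted by (chrom, pos) so a
# window query is a binary search on the position vector
sites_in_window <- function(dataset, chrom, start, end) {
  s <- dataset$sites
  idx <- which(s$chrom == chrom)
  if (!length(idx)) return(integer(0))
  p <- s$pos[idx]
  lo <- findInterval(start - 1L, p) + 1L
  hi <- findInterval(end, p)
  if (lo > hi) integer(0) else idx[lo:hi]
}
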