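#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString reverseComplement letterFrequency vcountPattern matchPattern
#'   subseq replaceAt getSeq
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames
#' @importFrom utils read.table write.table
#' @importFrom rtracklayer import
NULL

## ---- genome ----------------------------------------------------------------

#' Read a genome FASTA into a DNAStringSet
#'
#' Record ids are truncated at the first whitespace; lowercase letters are
#' upcased and any letter outside A/C/G/T/N is mapped to N. Duplicate record
#' ids are a hard error. `seqlengths`-style lengths are available via
#' `width()`.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
    seqs <- readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stop("duplicate scaffold id in ", path, ": ",
             paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
    # map IUPAC ambiguity letters to N; DNAStringSet already upcases
    chr <- as.character(seqs)
    chr <- chartr("MRWSYKVHDB", "NNNNNNNNNN", chr)
    out <- DNAStringSet(chr)
    names(out) <- names(seqs)
    out
}

genomeLengths <- function(genome) {
    stats::setNames(Biostrings::width(genome), names(genome))
}

## ---- annotation ------------------------------------------------------------

#' GeneAnnotation: genes, exon models, derived introns, promoters, repeats
#'
#' All ranges use the usual Bioconductor 1-based closed convention; the
#' 0-based half-open convention of BED is produced only at export.
#'
#' @slot genes `GRanges`, one per gene, with `gene_id` metadata.
#' @slot exons `GRangesList` keyed by gene id; per-gene exons are disjoint
#'   and sorted.
#' @slot introns `GRangesList`, gaps between consecutive exons.
#' @slot promoters `GRanges`, fixed-width region upstream of each TSS on the
#'   gene strand, clipped at scaffold bounds.
#' @slot repeats `GRanges` (possibly empty) with a `class` column.
#' @aliases GeneAnnotation-class
#' @exportClass GeneAnnotation
setClass("GeneAnnotation", representation(
    genes = "GRanges", exons = "GRangesList",
    introns = "GRangesList", promoters = "GRanges",
    repeats = "GRanges"))

setValidity("GeneAnnotation", function(object) {
    msg <- NULL
    ids <- mcols(object@genes)$gene_id
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "genes need unique gene_id metadata")
    if (!identical(names(object@exons), ids))
        msg <- c(msg, "exons must be keyed by gene_id in gene order")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "GeneAnnotation", function(object) {
    cat("GeneAnnotation:", length(object@genes), "genes,",
        sum(lengths(object@exons)), "exons,",
        length(object@repeats), "repeats\n")
})

#' @describeIn GeneAnnotation the gene-level `GRanges`
#' @param x A `GeneAnnotation`.
#' @export
genes <- function(x) x@genes

#' @describeIn GeneAnnotation per-gene exon `GRangesList`
#' @export
exonsBy <- function(x) x@exons

#' @describeIn GeneAnnotation per-gene intron `GRangesList`
#' @export
intronsBy <- function(x) x@introns

#' @describeIn GeneAnnotation promoter `GRanges`
#' @export
promoterRanges <- function(x) x@promoters

#' @describeIn GeneAnnotation repeat `GRanges`
#' @export
repeatRanges <- function(x) x@repeats

derivedIntrons <- function(exons) {
    ## gaps between consecutive exons of one gene
    endoapply(exons, function(e) {
        e <- GenomicRanges::sort(e)
        if (length(e) < 2L) return(e[0])
        GRanges(seqnames(e)[1],
                IRanges(end(e)[-length(e)] + 1L, start(e)[-1L] - 1L),
                strand = strand(e)[1])
    })
}

derivedPromoters <- function(geneGr, promoterLen, seqLens = NULL) {
    plus <- as.logical(strand(geneGr) == "+") | as.logical(strand(geneGr) == "*")
    st <- ifelse(plus, start(geneGr) - promoterLen, end(geneGr) + 1L)
    en <- ifelse(plus, start(geneGr) - 1L, end(geneGr) + promoterLen)
    st <- pmax(st, 1L)
    if (!is.null(seqLens)) {
        lim <- seqLens[as.character(seqnames(geneGr))]
        en <- pmin(en, lim)
    }
    en <- pmax(en, st - 1L)  # degenerate promoter at scaffold edge -> width 0+
    pr <- GRanges(seqnames(geneGr), IRanges(st, pmax(en, st)),
                  strand = strand(geneGr))
    mcols(pr)$gene_id <- mcols(geneGr)$gene_id
    pr
}

#' Assemble a GeneAnnotation from gene and exon ranges
#'
#' Exons of each gene are unioned (disjoint, sorted); introns are derived as
#' the gaps between consecutive exons; promoters as `promoterLen` bp upstream
#' of the TSS on the gene strand, clipped at scaffold bounds when `seqLens`
#' is given.
#'
#' @param geneGr `GRanges` with `gene_id`.
#' @param exonGr `GRanges` with `gene_id` linking each exon to its gene.
#' @param repeats optional repeat `GRanges`.
#' @param promoterLen promoter length in bp (default 1000).
#' @param seqLens named scaffold lengths for bound clipping/validation.
#' @return A [GeneAnnotation].
#' @export
geneAnnotation <- function(geneGr, exonGr, repeats = GRanges(),
                           promoterLen = 1000L, seqLens = NULL) {
    ids <- mcols(geneGr)$gene_id
    if (is.null(mcols(exonGr)$gene_id) && !is.null(names(exonGr)))
        mcols(exonGr)$gene_id <- names(exonGr)
    if (!is.null(seqLens)) {
        lim <- seqLens[as.character(seqnames(exonGr))]
        bad <- which(is.na(lim) | end(exonGr) > lim | start(exonGr) < 1L)
        if (length(bad))
            stop("exon outside scaffold bounds for gene ",
                 mcols(exonGr)$gene_id[bad[1]])
    }
    exl <- GenomicRanges::reduce(
        GenomicRanges::split(exonGr, factor(mcols(exonGr)$gene_id, levels = ids)))
    ## reduce() drops strand-aware order; restore gene strand
    exl <- endoapply(exl, GenomicRanges::sort)
    for (i in seq_along(ids)) strand(exl[[i]]) <- strand(geneGr)[i]
    new("GeneAnnotation",
        genes = geneGr, exons = exl, introns = derivedIntrons(exl),
        promoters = derivedPromoters(geneGr, as.integer(promoterLen), seqLens),
        repeats = repeats)
}

#' Read a GFF3 gene annotation
#'
#' Loads gene/mRNA/exon features, collapses each gene's exons to a disjoint
#' sorted set, derives introns and fixed-width promoters. GFF3's 1-based
#' closed coordinates are kept in the 1-based closed `GRanges` convention.
#'
#' @param path GFF3 file.
#' @param promoterLen promoter length in bp upstream of the TSS.
#' @param seqLens optional named scaffold lengths; exons outside bounds are
#'   an error naming the offending feature.
#' @return A [GeneAnnotation].
#' @export
readAnnotation <- function(path, promoterLen = 1000L, seqLens = NULL) {
    gff <- rtracklayer::import(path, format = "gff3")
    ty <- tolower(as.character(mcols(gff)$type))
    geneGr <- gff[ty == "gene"]
    mcols(geneGr) <- DataFrame(gene_id = as.character(mcols(geneGr)$ID))
    ex <- gff[ty == "exon"]
    parent <- as.character(unlist(mcols(ex)$Parent))
    ## map exon -> gene through mRNA parents when present
    mrna <- gff[ty == "mrna"]
    if (length(mrna)) {
        m2g <- stats::setNames(as.character(unlist(mcols(mrna)$Parent)),
                               as.character(mcols(mrna)$ID))
        hit <- parent %in% names(m2g)
        parent[hit] <- m2g[parent[hit]]
    }
    mcols(ex) <- DataFrame(gene_id = parent)
    geneAnnotation(geneGr, ex, promoterLen = promoterLen, seqLens = seqLens)
}

#' Read a repeat BED file (0-based half-open) into 1-based GRanges
#' @param path BED file with columns chrom, start, end and optionally name.
#' @return `GRanges` with a `class` column.
#' @export
readRepeats <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "start", "end", "class")[
                         seq_len(max(3, ncol(read.table(path, sep = "\t", nrows = 1))))],
                     stringsAsFactors = FALSE)
    if (!"class" %in% colnames(df)) df$class <- "repeat"
    GRanges(df$chrom, IRanges(df$start + 1L, df$end), class = df$class)
}

#' Write GRanges as BED (converting to 0-based half-open)
#' @param gr `GRanges`; a `name` metadata column is used when present.
#' @param path output file.
#' @export
writeBed <- function(gr, path) {
    nm <- mcols(gr)$name
    if (is.null(nm)) nm <- rep(".", length(gr))
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr), name = nm)
    df <- df[order(df$chrom, df$start), ]
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## ---- cytosine reports ------------------------------------------------------

#' Read a Bismark-style cytosine report for one sample
#'
#' Expects tab-separated columns scaffold, 1-based position, strand (+/-),
#' methylated count, unmethylated count, context. Only CpG-context rows are
#' kept; the plus- and minus-strand rows of one CpG dyad are combined into a
#' single site keyed by the plus-strand C (minus-strand G position minus 1),
#' with counts summed.
#'
#' @param path TSV file (a `#` header line is tolerated).
#' @return data.frame with columns `scaffold`, `pos` (1-based plus-strand C),
#'   `m`, `u`, sorted by (scaffold, pos).
#' @export
readCytosineReport <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                     col.names = c("scaffold", "pos", "strand", "m", "u",
                                   "context"),
                     colClasses = c("character", "integer", "character",
                                    "integer", "integer", "character"),
                     stringsAsFactors = FALSE)
    if (any(df$m < 0 | df$u < 0))
        stop("negative counts in cytosine report ", path)
    df <- df[df$context == "CG", , drop = FALSE]
    cpos <- ifelse(df$strand == "-", df$pos - 1L, df$pos)
    key <- paste(df$scaffold, cpos)
    m <- rowsum(df$m, key)
    u <- rowsum(df$u, key)
    first <- !duplicated(key)
    out <- data.frame(scaffold = df$scaffold[first], pos = cpos[first],
                      m = as.integer(m[match(key[first], rownames(m))]),
                      u = as.integer(u[match(key[first], rownames(u))]),
                      stringsAsFactors = FALSE)
    out[order(out$scaffold, out$pos), , drop = FALSE]
}

#' Write a per-sample cytosine report (both dyad strands, CG context)
#'
#' The dyad's pooled counts are written on the plus-strand row; the
#' minus-strand row is written with zero counts so the file round-trips
#' through [readCytosineReport()].
#'
#' @param df data.frame with `scaffold`, `pos` (1-based plus-strand C), `m`, `u`.
#' @param path output file.
#' @export
writeCytosineReport <- function(df, path) {
    df <- df[order(df$scaffold, df$pos), , drop = FALSE]
    out <- rbind(
        data.frame(scaffold = df$scaffold, pos = df$pos, strand = "+",
                   m = df$m, u = df$u, context = "CG"),
        data.frame(scaffold = df$scaffold, pos = df$pos + 1L, strand = "-",
                   m = 0L, u = 0L, context = "CG"))
    out <- out[order(out$scaffold, out$pos), ]
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Assemble per-sample cytosine reports into a BSCounts object
#'
#' Sites are unioned across samples; samples without data at a site get
#' zero counts.
#'
#' @param tables named list of data.frames as returned by
#'   [readCytosineReport()]; names are sample ids.
#' @param design data.frame with columns `sample`, `caste`, `sex`,
#'   `replicate`; every table name must appear.
#' @return A [BSCounts].
#' @export
assembleBSCounts <- function(tables, design) {
    miss <- setdiff(names(tables), design$sample)
    if (length(miss))
        stop("samples missing from design: ", paste(miss, collapse = ", "))
    design <- design[match(names(tables), design$sample), , drop = FALSE]
    keys <- unique(unlist(lapply(tables, function(t) paste(t$scaffold, t$pos))))
    sc <- sub(" .*", "", keys)
    po <- as.integer(sub(".* ", "", keys))
    o <- order(sc, po)
    keys <- keys[o]; sc <- sc[o]; po <- po[o]
    M <- U <- matrix(0L, length(keys), length(tables),
                     dimnames = list(NULL, names(tables)))
    for (s in names(tables)) {
        t <- tables[[s]]
        i <- match(paste(t$scaffold, t$pos), keys)
        M[i, s] <- t$m; U[i, s] <- t$u
    }
    BSCounts(GRanges(sc, IRanges(po, width = 1L)), M, U, design)
}

## ---- result tables ---------------------------------------------------------

#' Write a result table as TSV with a '#'-prefixed header line
#' @param df data.frame.
#' @param path output file.
#' @export
writeResultTable <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(colnames(df), collapse = "\t")), con)
    if (nrow(df))
        write.table(df, con, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a table written by [writeResultTable()]
#' @param path TSV file whose first line is a '#'-prefixed header.
#' @return data.frame with the original column names.
#' @export
readResultTable <- function(path) {
    hdr <- strsplit(sub("^#", "", readLines(path, n = 1L)), "\t")[[1]]
    df <- tryCatch(
        read.table(path, sep = "\t", header = FALSE, skip = 1L,
                   col.names = hdr, stringsAsFactors = FALSE),
        error = function(e) {
            empty <- as.data.frame(stats::setNames(
                replicate(length(hdr), logical(0), simplify = FALSE), hdr))
            empty
        })
    df
}
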