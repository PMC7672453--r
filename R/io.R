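#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo seqinfo<-
#'   seqlevels keepSeqlevels
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
#' @importFrom utils read.table write.table
NULL

#' Declare a genome as an ordered set of chromosomes with lengths
#'
#' Thin wrapper around [GenomeInfoDb::Seqinfo] so every module shares one
#' genome declaration.
#'
#' @param chromNames character vector of unique chromosome names.
#' @param chromLengths positive integer lengths in bp.
#' @return A `Seqinfo` object.
#' @examples
#' genomeDeclaration("chr1", 1e6)
#' @export
genomeDeclaration <- function(chromNames, chromLengths) {
    if (anyDuplicated(chromNames)) stop("chromosome names must be unique")
    if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
    Seqinfo(seqnames = as.character(chromNames),
            seqlengths = as.integer(chromLengths))
}

.checkChroms <- function(chroms, genome) {
    if (is.null(genome)) return(invisible(NULL))
    bad <- setdiff(unique(as.character(chroms)), seqnames(genome))
    if (length(bad))
        stop("unknown chromosome(s) not in the declared genome: ",
             paste(bad, collapse = ", "))
    invisible(NULL)
}

#' Read aligned fragments from SAM/BAM or a BED-like read table
#'
#' Returns one `GRanges` record per usable read or fragment. Unaligned
#' records are skipped. The mapping-quality filter is strict: a record
#' survives only if `mapq > minMapq` (the conventional "above 20" filter
#' keeps MAPQ 21 and up). PCR-duplicate-flagged records are kept by default —
#' the mark is carried in `mcols()$isDuplicate` so callers can drop them.
#' Properly paired reads are collapsed to a single fragment spanning the
#' outer template coordinates (leftmost mate position + TLEN); the fragment
#' carries the pair's minimum MAPQ.
#'
#' @param path SAM, BAM, or BED-like file. BED columns are
#'   chrom/start/end/name/mapq/strand with 0-based half-open coordinates.
#' @param minMapq keep records with `mapq > minMapq` (default 20).
#' @param keepDuplicates keep duplicate-flagged records (default `TRUE`).
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"bed"`.
#' @param genome optional `Seqinfo`; records on undeclared chromosomes are an
#'   error, and the result carries the declaration.
#' @return `GRanges` with metadata columns `mapq` (integer) and
#'   `isDuplicate` (logical). Paired fragments additionally have
#'   `isFragment = TRUE` so downstream counting skips read extension.
#' @export
readAlignments <- function(path, minMapq = 20, keepDuplicates = TRUE,
                           format = c("auto", "sam", "bam", "bed"),
                           genome = NULL) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, sam = "sam", bam = "bam", bed = "bed",
                         stop("cannot guess format from extension '.", ext,
                              "'; pass format="))
    }
    if (minMapq < 0) stop("minMapq must be >= 0")
    gr <- if (format == "bed") .readReadBed(path)
          else .readReadBam(path, format)
    .checkChroms(seqnames(gr), genome)
    gr <- gr[mcols(gr)$mapq > minMapq]
    if (!keepDuplicates) gr <- gr[!mcols(gr)$isDuplicate]
    if (!is.null(genome)) {
        GenomeInfoDb::seqlevels(gr) <- seqnames(genome)
        seqinfo(gr) <- genome
    }
    gr
}

.readReadBam <- function(path, format) {
    if (format == "sam") {
        dest <- tempfile(fileext = "")
        path <- suppressMessages(asBam(path, destination = dest,
                                       overwrite = TRUE, indexDestination = FALSE))
    }
    what <- c("rname", "pos", "strand", "qwidth", "mapq", "flag", "isize")
    p <- ScanBamParam(what = what,
                      flag = scanBamFlag(isUnmappedQuery = FALSE))
    res <- scanBam(path, param = p)[[1]]
    if (length(res$pos) == 0L)
        return(GRanges(mapq = integer(0), isDuplicate = logical(0),
                       isFragment = logical(0)))
    flag <- res$flag
    isDup <- bitwAnd(flag, 1024L) > 0L
    isPaired <- bitwAnd(flag, 1L) > 0L & bitwAnd(flag, 2L) > 0L
    mapq <- res$mapq
    mapq[is.na(mapq)] <- 0L
    ## paired: keep the leftmost mate (TLEN > 0), span the template
    keepPair <- isPaired & !is.na(res$isize) & res$isize > 0L
    single <- !isPaired
    grS <- GRanges(res$rname[single],
                   IRanges(res$pos[single], width = res$qwidth[single]),
                   strand = res$strand[single],
                   mapq = mapq[single], isDuplicate = isDup[single],
                   isFragment = rep(FALSE, sum(single)))
    grP <- GRanges(res$rname[keepPair],
                   IRanges(res$pos[keepPair], width = res$isize[keepPair]),
                   strand = rep("*", sum(keepPair)),
                   mapq = mapq[keepPair], isDuplicate = isDup[keepPair],
                   isFragment = rep(TRUE, sum(keepPair)))
    sort(c(grS, grP), ignore.strand = TRUE)
}

.readReadBed <- function(path) {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 3L) stop("read BED needs at least 3 columns")
    bad <- which(tab[[2]] >= tab[[3]])
    if (length(bad))
        stop("start >= end at line ", bad[1], " of ", path)
    mapq <- if (ncol(tab) >= 5L) as.integer(tab[[5]]) else 255L
    strand <- if (ncol(tab) >= 6L) tab[[6]] else "*"
    GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]), strand = strand,
            mapq = mapq, isDuplicate = FALSE, isFragment = FALSE)
}

#' Read genomic intervals from BED or a tab-separated table
#'
#' BED is parsed as 0-based half-open and converted to the in-memory 1-based
#' `GRanges` convention; a TSV dialect with a header row
#' (`chrom`, `start`, `end`, optional `name`, `score`) is treated the same
#' way. Output is sorted by (chrom, start).
#'
#' @param path file path.
#' @param dialect `"bed"` or `"tsv"`.
#' @param genome optional `Seqinfo` for validation.
#' @return sorted `GRanges`, with `name`/`score` metadata columns when
#'   present in the file.
#' @export
readIntervals <- function(path, dialect = c("bed", "tsv"), genome = NULL) {
    dialect <- match.arg(dialect)
    header <- dialect == "tsv"
    if (length(readLines(path, n = 1)) == 0L) return(GRanges())
    tab <- tryCatch(
        read.table(path, sep = "\t", header = header,
                   stringsAsFactors = FALSE),
        error = function(e) stop("malformed interval file ", path, ": ",
                                 conditionMessage(e)))
    if (nrow(tab) == 0L) return(GRanges())
    if (ncol(tab) < 3L) stop("interval file needs >= 3 columns")
    start0 <- as.numeric(tab[[2]]); end0 <- as.numeric(tab[[3]])
    bad <- which(!(start0 < end0) | start0 < 0)
    if (length(bad))
        stop("invalid interval (start >= end or negative) at line ",
             bad[1] + as.integer(header), " of ", path)
    gr <- GRanges(tab[[1]], IRanges(start0 + 1, end0))
    if (ncol(tab) >= 4L) mcols(gr)$name <- as.character(tab[[4]])
    if (ncol(tab) >= 5L) mcols(gr)$score <- as.numeric(tab[[5]])
    .checkChroms(seqnames(gr), genome)
    if (!is.null(genome)) {
        GenomeInfoDb::seqlevels(gr) <- seqnames(genome)
        seqinfo(gr) <- genome
    }
    sort(gr, ignore.strand = TRUE)
}

#' Write intervals with values as bedGraph
#'
#' Coordinates are emitted 0-based half-open. Bins must be sorted and
#' non-overlapping. With `merge = TRUE`, runs of adjacent bins with equal
#' values are collapsed to one line; the default keeps one line per bin for
#' bit-exact round trips.
#'
#' @param bins sorted, disjoint `GRanges`.
#' @param values numeric vector, one value per bin.
#' @param path output path.
#' @param merge collapse adjacent equal-valued bins.
#' @param trackName name written in the track header line.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(bins, values, path, merge = FALSE,
                          trackName = "coverage") {
    if (length(bins) != length(values))
        stop("one value per bin required")
    if (length(bins)) {
        o <- order(as.character(seqnames(bins)), start(bins))
        if (!identical(o, seq_along(bins))) stop("bins must be sorted")
        if (!IRanges::isDisjoint(bins)) stop("bins must be non-overlapping")
    }
    chrom <- as.character(seqnames(bins))
    s0 <- start(bins) - 1L
    e0 <- end(bins)
    v <- as.numeric(values)
    if (merge && length(bins) > 1L) {
        newRun <- c(TRUE, !(chrom[-1] == chrom[-length(chrom)] &
                            s0[-1] == e0[-length(e0)] &
                            v[-1] == v[-length(v)]))
        runId <- cumsum(newRun)
        chrom <- chrom[newRun]
        s0 <- s0[newRun]
        e0 <- as.integer(tapply(e0, runId, max))
        v <- v[newRun]
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", trackName), con)
    if (length(chrom))
        writeLines(sprintf("%s\t%d\t%d\t%s", chrom, s0, e0,
                           format(v, trim = TRUE, scientific = FALSE)), con)
    invisible(path)
}

#' Write intervals as 6-column BED
#'
#' @param gr `GRanges`; `mcols()$name` and `$score` are used when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
    name <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
            else if (!is.null(names(gr))) names(gr)
            else sprintf("region_%d", seq_along(gr))
    score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0
    strand <- as.character(strand(gr))
    strand[strand == "*"] <- "."
    tab <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      name = name, score = score, strand = strand)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects a tab-separated file with a header row and columns `gene_id`,
#' `chrom`, `tss` (0-based position of the transcription start site) and
#' `strand`; one row per gene (one TSS per gene, e.g. the longest
#' transcript's).
#'
#' @param path file path.
#' @param genome optional `Seqinfo`.
#' @return `GRanges` of width-1 TSS positions, named by `gene_id`, with a
#'   `gene_id` metadata column.
#' @export
readTssTable <- function(path, genome = NULL) {
    tab <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% colnames(tab)))
        stop("TSS table needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$gene_id)) stop("gene_id values must be unique")
    tssAnnotation(tab$gene_id, tab$chrom, tab$tss, tab$strand, genome)
}

#' Build a TSS annotation in memory
#'
#' @param geneId unique gene identifiers.
#' @param chrom chromosome names.
#' @param tss 0-based TSS positions.
#' @param strand `"+"`/`"-"`.
#' @param genome optional `Seqinfo`.
#' @return named width-1 `GRanges`, as [readTssTable()].
#' @export
tssAnnotation <- function(geneId, chrom, tss, strand = "+", genome = NULL) {
    if (anyDuplicated(geneId)) stop("gene_id values must be unique")
    .checkChroms(chrom, genome)
    pos1 <- as.integer(tss) + 1L
    if (!is.null(genome) &&
        any(pos1 > seqlengths(genome)[as.character(chrom)] | pos1 < 1L))
        stop("TSS beyond chromosome bounds")
    gr <- GRanges(chrom, IRanges(pos1, width = 1L),
                  strand = strand, gene_id = as.character(geneId))
    names(gr) <- geneId
    if (!is.null(genome)) {
        GenomeInfoDb::seqlevels(gr) <- seqnames(genome)
        seqinfo(gr) <- genome
    }
    gr
}

#' Promoter windows around TSS positions
#'
#' The promoter of a gene is the half-open interval
#' `[tss - radius, tss + radius)` in 0-based coordinates (width
#' `2 * radius`), strand-independent.
#'
#' @param tss TSS `GRanges` from [tssAnnotation()].
#' @param radius half-width in bp (default 1000, i.e. TSS +/- 1 kb).
#' @return named `GRanges` of promoter intervals.
#' @export
promoterRanges <- function(tss, radius = 1000) {
    prom <- GRanges(seqnames(tss),
                    IRanges(pmax(start(tss) - radius, 1L),
                            start(tss) + radius - 1L),
                    strand = strand(tss), seqinfo = seqinfo(tss))
    mcols(prom)$gene_id <- mcols(tss)$gene_id
    names(prom) <- names(tss)
    suppressWarnings(IRanges::trim(prom))
}
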