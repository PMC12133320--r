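#' Read a designed oligo library from FASTA
#'
#' Reads the oligo catalogue (plain or gzip-compressed FASTA; compression
#' is detected from the file content, not the extension). Record order is
#' preserved, sequences are uppercased, and ids are the first whitespace-
#' delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return An `oligo_library`: a named character vector of DNA sequences,
#'   one per designed oligo.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">O1", "ACGT", ">O2", "TTAA"), fa)
#' lib <- read_fasta(fa)
#' n_oligos(lib)
#' @export
read_fasta <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(set))
    dup <- ids[duplicated(ids)]
    if (length(dup) > 0L)
        stop("duplicate oligo id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
    seqs <- toupper(as.character(set))
    names(seqs) <- ids
    odd <- grepl("[^ACGTN]", seqs)
    if (any(odd))
        warning(sum(odd), " oligo sequence(s) contain non-ACGTN characters ",
                "(IUPAC ambiguity codes kept as-is)")
    structure(seqs, class = "oligo_library")
}

#' Number of oligos in a library
#' @param lib An `oligo_library`.
#' @return Integer count of entries.
#' @export
n_oligos <- function(lib) length(lib)

#' @export
print.oligo_library <- function(x, ...) {
    cat("<oligo_library> ", length(x), " oligos, lengths ",
        min(nchar(x)), "-", max(nchar(x)), " nt\n", sep = "")
    invisible(x)
}

#' Stream a FASTQ file in constant memory
#'
#' Returns a chunked reader over a FASTQ file (plain or gzipped; detected
#' from content). Each call to `$read_chunk()` yields a data.frame with
#' columns `id`, `sequence`, `quality` for up to `chunk_records` records,
#' or `NULL` at end of file. A truncated trailing record (file length not
#' a multiple of 4 lines) is a hard error naming the record index.
#'
#' @param path Path to a FASTQ file.
#' @param chunk_records Records per chunk.
#' @return A `fastq_stream` object with elements `read_chunk` (function),
#'   `close` (function) and `path`.
#' @export
fastq_stream <- function(path, chunk_records = 100000L) {
    if (!file.exists(path)) stop("FASTQ file not found: ", path)
    con <- gzfile(path, open = "rt")   # reads plain files transparently
    n_seen <- 0L
    done <- FALSE
    read_chunk <- function() {
        if (done) return(NULL)
        lines <- readLines(con, n = chunk_records * 4L)
        if (length(lines) == 0L) {
            done <<- TRUE
            close(con)
            return(NULL)
        }
        if (length(lines) %% 4L != 0L) {
            close(con); done <<- TRUE
            stop("truncated FASTQ record at record ",
                 n_seen + length(lines) %/% 4L + 1L, " in ", path)
        }
        i <- seq.int(1L, length(lines), by = 4L)
        ids <- lines[i]
        if (!all(startsWith(ids, "@")))
            stop("malformed FASTQ header near record ", n_seen + 1L, " in ", path)
        rec <- data.frame(
            id = sub("\\s.*$", "", substring(ids, 2L)),
            sequence = toupper(lines[i + 1L]),
            quality = lines[i + 3L],
            stringsAsFactors = FALSE
        )
        n_seen <<- n_seen + nrow(rec)
        rec
    }
    structure(list(read_chunk = read_chunk,
                   close = function() try(close(con), silent = TRUE),
                   path = path),
              class = "fastq_stream")
}

#' Read an entire FASTQ file into memory
#'
#' Convenience wrapper over [fastq_stream()] for small files.
#' @inheritParams fastq_stream
#' @return data.frame with columns `id`, `sequence`, `quality` (possibly
#'   zero rows for an empty file).
#' @export
read_fastq <- function(path) {
    st <- fastq_stream(path)
    out <- list()
    repeat {
        ch <- st$read_chunk()
        if (is.null(ch)) break
        out[[length(out) + 1L]] <- ch
    }
    if (length(out) == 0L)
        return(data.frame(id = character(), sequence = character(),
                          quality = character(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Write a tab-separated table with a single header line
#'
#' All pipeline artifacts are TSV with one header line; row order is
#' written as given so outputs are byte-reproducible.
#'
#' @param rows data.frame (may have zero rows).
#' @param path Output path.
#' @param header Optional replacement column names.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, header = NULL) {
    rows <- as.data.frame(rows)
    if (!is.null(header)) {
        if (length(header) != ncol(rows))
            stop("header length does not match number of columns")
        colnames(rows) <- header
    }
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read back a TSV written by [write_table()]
#' @param path Path to a TSV file.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = NA)
}

#' Reverse-complement DNA strings
#' @param seqs Character vector of DNA sequences.
#' @return Character vector of reverse complements (non-ACGT bases
#'   become N).
#' @export
revcomp <- function(seqs) revcomp_cpp(as.character(seqs))

# FASTQ writer used by the simulator; gzip if path ends in .gz.
write_fastq_ <- function(ids, seqs, quals, path) {
    lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}
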