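#' Parse samtools-mpileup text
#'
#' Decodes the standard samtools pileup dialect: per line `chrom pos ref
#' depth bases quals`, where the base string uses `.`/`,` for matches on the
#' forward/reverse mapping strand, upper/lowercase letters for mismatches,
#' `^X` before the first base of a read (X encoding its mapping quality,
#' Phred+33), `$` after its last base, `*` for a deletion placeholder and
#' `+n<seq>`/`-n<seq>` for indels attached to the preceding observation
#' (parsed and recorded, excluded from base observations).
#'
#' Reads are tracked across columns from the `^`/`$` markers (mpileup lists
#' surviving reads in a stable relative order), giving every observation an
#' opaque `read_id` that the caller's neighborhood filter uses.
#'
#' An extended dialect with two extra tab-separated columns -- comma-joined
#' 1-based read positions (as in `samtools mpileup -O`) and read lengths --
#' supplies the distances of each observation to the read's 5' and 3' ends;
#' without them the distances are `NA` (unknown).
#'
#' @param x Path to a pileup file, or a character vector of pileup lines
#'   (anything containing a tab is treated as lines).
#' @return Object of class `pileup`: list with `obs` (data frame: `pos`,
#'   `ref`, `read_id`, `base`, `strand` (`+`/`-`), `qual`, `mapq`, `dist5`,
#'   `dist3`), `sites` (data frame `pos`, `ref`, `depth`), and `indels`
#'   (data frame of attached indel events).
#' @export
parse_pileup <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\t", x)) readLines(x, warn = FALSE) else x
  lines <- lines[nzchar(lines)]
  active_ids <- character(0)   # surviving reads, in column order
  active_mapq <- integer(0)
  next_id <- 1L
  obs_list <- vector("list", length(lines))
  indel_list <- list()
  site_pos <- integer(length(lines))
  site_ref <- character(length(lines))
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L)
      stop("pileup line ", li, ": expected at least 6 tab-separated fields")
    pos <- as.integer(f[2L]); ref <- toupper(f[3L])
    bases <- f[5L]; quals <- f[6L]
    chars <- strsplit(bases, "")[[1L]]
    qchars <- strsplit(quals, "")[[1L]]
    b <- character(0); strand <- character(0); is_new <- logical(0)
    ends <- logical(0); newmapq <- integer(0)
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "^") {
        if (i + 1L > length(chars))
          stop("pileup line ", li, ": dangling ^")
        newmapq <- c(newmapq, utf8ToInt(chars[i + 1L]) - 33L)
        is_new <- c(is_new, TRUE)
        i <- i + 2L
        next
      }
      if (ch == "$") {
        if (!length(ends)) stop("pileup line ", li, ": $ before any base")
        ends[length(ends)] <- TRUE
        i <- i + 1L
        next
      }
      if (ch %in% c("+", "-")) {
        m <- regmatches(substring(bases, i),
                        regexec("^[+-]([0-9]+)", substring(bases, i)))[[1L]]
        if (length(m) < 2L) stop("pileup line ", li, ": malformed indel")
        ilen <- as.integer(m[2L])
        seq_start <- i + 1L + nchar(m[2L])
        indel_list[[length(indel_list) + 1L]] <- data.frame(
          pos = pos, type = ch, length = ilen,
          seq = paste(chars[seq_start:(seq_start + ilen - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
        i <- seq_start + ilen
        next
      }
      # a base observation (possibly flagged new by a preceding ^)
      if (length(is_new) < length(b) + 1L) is_new <- c(is_new, FALSE)
      if (ch %in% c(".", ",")) {
        b <- c(b, ref); strand <- c(strand, if (ch == ".") "+" else "-")
      } else if (ch == "*") {
        b <- c(b, "*"); strand <- c(strand, NA_character_)
      } else if (grepl("^[ACGTNacgtn]$", ch)) {
        b <- c(b, toupper(ch))
        strand <- c(strand, if (ch == toupper(ch)) "+" else "-")
      } else {
        stop("pileup line ", li, ": unexpected character '", ch, "'")
      }
      ends <- c(ends, FALSE)
      i <- i + 1L
    }
    if (length(b) != length(qchars))
      stop("pileup line ", li, ": ", length(b), " base observations but ",
           length(qchars), " quality characters")
    is_new <- c(is_new, rep(FALSE, length(b) - length(is_new)))
    # assign read ids: new reads get fresh ids, others consume survivors in order
    ids <- character(length(b)); mapq <- integer(length(b))
    surv_ptr <- 1L; new_ptr <- 1L
    new_active_ids <- character(0); new_active_mapq <- integer(0)
    for (k in seq_along(b)) {
      if (is_new[k]) {
        ids[k] <- paste0("r", next_id)
        mapq[k] <- if (new_ptr <= length(newmapq)) newmapq[new_ptr] else NA_integer_
        next_id <- next_id + 1L
        new_ptr <- new_ptr + 1L
      } else if (surv_ptr <= length(active_ids)) {
        ids[k] <- active_ids[surv_ptr]
        mapq[k] <- active_mapq[surv_ptr]
        surv_ptr <- surv_ptr + 1L
      } else {
        # read seen without '^' (file truncated or isolated column):
        # track it with a fresh id and unknown mapping quality
        ids[k] <- paste0("r", next_id)
        mapq[k] <- NA_integer_
        next_id <- next_id + 1L
      }
      if (!ends[k]) {
        new_active_ids <- c(new_active_ids, ids[k])
        new_active_mapq <- c(new_active_mapq, mapq[k])
      }
    }
    active_ids <- new_active_ids
    active_mapq <- new_active_mapq
    dist5 <- rep(NA_integer_, length(b)); dist3 <- rep(NA_integer_, length(b))
    if (length(f) >= 8L && nzchar(f[7L]) && nzchar(f[8L])) {
      rp <- as.integer(strsplit(f[7L], ",", fixed = TRUE)[[1L]])
      rl <- as.integer(strsplit(f[8L], ",", fixed = TRUE)[[1L]])
      if (length(rp) != length(b) || length(rl) != length(b))
        stop("pileup line ", li, ": read-position columns do not match depth")
      dist5 <- rp - 1L
      dist3 <- rl - rp
    }
    obs_list[[li]] <- data.frame(
      pos = pos, ref = ref, read_id = ids, base = b, strand = strand,
      qual = utf8ToInt(quals) - 33L, mapq = mapq,
      dist5 = dist5, dist3 = dist3, stringsAsFactors = FALSE)
    site_pos[li] <- pos
    site_ref[li] <- ref
  }
  obs <- do.call(rbind, obs_list)
  if (is.null(obs))
    obs <- data.frame(pos = integer(), ref = character(), read_id = character(),
                      base = character(), strand = character(), qual = integer(),
                      mapq = integer(), dist5 = integer(), dist3 = integer(),
                      stringsAsFactors = FALSE)
  structure(
    list(obs = obs,
         sites = data.frame(pos = site_pos, ref = site_ref,
                            depth = as.integer(table(factor(obs$pos, levels = site_pos))),
                            stringsAsFactors = FALSE),
         indels = if (length(indel_list)) do.call(rbind, indel_list) else
           data.frame(pos = integer(), type = character(), length = integer(),
                      seq = character(), stringsAsFactors = FALSE)),
    class = "pileup"
  )
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d positions, %d observations, %d indel events\n",
              nrow(x$sites), nrow(x$obs), nrow(x$indels)))
  invisible(x)
}

# Quality gating: drop deletion placeholders, N bases, and observations
# below the base/mapping quality thresholds. NA mapping quality passes
# (unknown, e.g. truncated file head).
gate_observations <- function(obs, params) {
  keep <- obs$base %in% c("A", "C", "G", "T") &
    obs$qual >= params$min_base_quality &
    (is.na(obs$mapq) | obs$mapq >= params$min_mapping_quality)
  obs[keep, , drop = FALSE]
}
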