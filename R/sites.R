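# Six probing positions per tooth, coded as in standard periodontal charting.
# "lingual" covers the palatal surface in the maxilla.
.SITE_CODES <- data.frame(
  code     = c("MB", "B", "DB", "ML", "L", "DL"),
  surface  = rep(c("buccal", "lingual"), each = 3),
  position = rep(c("mesial", "central", "distal"), 2),
  stringsAsFactors = FALSE
)

.ALL_TEETH <- c(11:17, 21:27, 31:37, 41:47)

#' Full-dentition site universe
#'
#' Enumerates the 168 probing sites of a complete adult dentition excluding
#' third molars: 28 teeth (FDI codes 11-17, 21-27, 31-37, 41-47), each with
#' six sites (buccal/lingual surface crossed with mesial/central/distal
#' position).
#'
#' @param include_molars If `FALSE`, first and second molars (FDI positions
#'   6-7) are dropped, leaving the 20-tooth premolar/anterior universe
#'   (120 sites).
#' @return A data frame with one row per site and columns `tooth` (FDI code),
#'   `surface`, `position`, `label` (e.g. `"15-ML"`), `quadrant`, `jaw`
#'   (`"max"`/`"mand"`), `pos` (distance from midline, 1-7), `tooth_type`
#'   (e.g. `"max5"`), and `side` (`"right"`/`"left"`).
#' @export
#' @examples
#' nrow(site_universe())                        # 168
#' nrow(site_universe(include_molars = FALSE))  # 120
site_universe <- function(include_molars = TRUE) {
  teeth <- .ALL_TEETH
  if (!include_molars) teeth <- teeth[teeth %% 10 <= 5]
  grid <- expand.grid(tooth = teeth, idx = seq_len(6), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$tooth, grid$idx), ]
  out <- data.frame(
    tooth    = grid$tooth,
    surface  = .SITE_CODES$surface[grid$idx],
    position = .SITE_CODES$position[grid$idx],
    stringsAsFactors = FALSE
  )
  out$label      <- site_label(out$tooth, out$surface, out$position)
  out$quadrant   <- out$tooth %/% 10
  out$jaw        <- ifelse(out$quadrant <= 2, "max", "mand")
  out$pos        <- out$tooth %% 10
  out$tooth_type <- paste0(out$jaw, out$pos)
  out$side       <- ifelse(out$quadrant %in% c(1, 4), "right", "left")
  rownames(out) <- NULL
  out
}

#' Site labels
#'
#' Builds the canonical `"<tooth>-<code>"` label (e.g. `"15-ML"` for the
#' mesiolingual site of the maxillary right second premolar) and parses it
#' back.
#'
#' @param tooth FDI tooth code(s).
#' @param surface `"buccal"` or `"lingual"`.
#' @param position `"mesial"`, `"central"` or `"distal"`.
#' @return `site_label()` a character vector; `parse_site_label()` a data
#'   frame with columns `tooth`, `surface`, `position`.
#' @export
site_label <- function(tooth, surface, position) {
  key <- paste(surface, position)
  codes <- .SITE_CODES$code[match(key, paste(.SITE_CODES$surface, .SITE_CODES$position))]
  if (anyNA(codes)) stop("invalid surface/position combination")
  paste0(tooth, "-", codes)
}

#' @rdname site_label
#' @param label Labels produced by `site_label()`.
#' @export
parse_site_label <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed site label(s): ", paste(label[bad], collapse = ", "))
  tooth <- as.integer(vapply(parts, `[`, "", 1L))
  code <- vapply(parts, `[`, "", 2L)
  idx <- match(code, .SITE_CODES$code)
  if (anyNA(idx) || anyNA(tooth)) stop("malformed site label(s)")
  data.frame(tooth = tooth,
             surface = .SITE_CODES$surface[idx],
             position = .SITE_CODES$position[idx],
             stringsAsFactors = FALSE)
}

#' Contralateral mirror of teeth and sites
#'
#' Maps an FDI tooth code to its contralateral partner (quadrants 1<->2 and
#' 3<->4; e.g. 15 <-> 25, 34 <-> 44). Mirroring a site preserves surface and
#' position.
#'
#' @param tooth FDI tooth code(s).
#' @return `mirror_tooth()` the mirrored FDI code(s); `mirror_site_label()`
#'   the mirrored site label(s).
#' @export
#' @examples
#' mirror_tooth(15)            # 25
#' mirror_site_label("34-MB")  # "44-MB"
mirror_tooth <- function(tooth) {
  q <- tooth %/% 10
  mq <- c(2, 1, 4, 3)[q]
  mq * 10 + tooth %% 10
}

#' @rdname mirror_tooth
#' @param label Site label(s) as from [site_label()].
#' @export
mirror_site_label <- function(label) {
  p <- parse_site_label(label)
  site_label(mirror_tooth(p$tooth), p$surface, p$position)
}

# tooth_type helper for bare tooth codes
.tooth_type <- function(tooth) {
  paste0(ifelse(tooth %/% 10 <= 2, "max", "mand"), tooth %% 10)
}
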