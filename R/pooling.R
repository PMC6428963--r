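#' Build a three-dimensional row/column/split-box pooling design
#'
#' Clones fill microtiter plates in row-major well order, plates are
#' grouped into blocks, and within each block three pool dimensions are
#' formed: a *row pool* is one plate row taken across a fixed pair of
#' consecutive plates, a *column pool* is one plate column across a
#' fixed triple of consecutive plates, and a *split-box pool* is one
#' `box_rows x box_cols` sub-block of a single plate.  With the default
#' 384-well geometry (16 x 24 wells, 6-plate blocks, 8 x 8 boxes) a
#' full block has 48-clone row pools, 48-clone column pools and
#' 64-clone box pools -- 48 + 48 + 36 = 132 pools over 2,304 clones --
#' and every clone lies in exactly one pool of each dimension, the
#' triple identifying it uniquely.  A trailing partial block simply has
#' smaller pools.
#'
#' Desk-scale simulations may shrink the geometry (fewer wells per
#' plate) to keep the number of blocks large relative to genome
#' coverage, the regime in which pooled deconvolution is informative.
#'
#' @param clone_ids character vector of clone ids, or a single integer
#'   n (ids `BAC000001 ...` are generated).
#' @param plate_rows,plate_cols wells per plate (default 16 x 24).
#' @param box_rows,box_cols split-box sub-block size; must divide the
#'   plate dimensions (default 8 x 8).
#' @param plates_per_row_pool,plates_per_col_pool how many consecutive
#'   plates a row/column pool spans (defaults 2 and 3).
#' @param block_plates plates per block (default 6); must be a multiple
#'   of both pool spans.
#' @return object of class `wgp_pooling_design`: list with `table`
#'   (data.frame `clone_id`, `block`, `plate`, `well_row`, `well_col`,
#'   `row_pool`, `col_pool`, `box_pool`), `pools` (data.frame
#'   `pool_id`, `block`, `dim`, `size`) and `geometry`.
#' @export
build_pooling_design <- function(clone_ids,
                                 plate_rows = 16L, plate_cols = 24L,
                                 box_rows = 8L, box_cols = 8L,
                                 plates_per_row_pool = 2L,
                                 plates_per_col_pool = 3L,
                                 block_plates = 6L) {
  if (is.numeric(clone_ids) && length(clone_ids) == 1L)
    clone_ids <- sprintf("BAC%06d", seq_len(as.integer(clone_ids)))
  n <- length(clone_ids)
  if (n < 1L) stopf("at least one clone is required")
  if (anyDuplicated(clone_ids)) stopf("clone ids must be unique")
  if (plate_rows %% box_rows != 0L || plate_cols %% box_cols != 0L)
    stopf("design infeasible: box size %dx%d does not tile the %dx%d plate",
          box_rows, box_cols, plate_rows, plate_cols)
  if (block_plates %% plates_per_row_pool != 0L ||
      block_plates %% plates_per_col_pool != 0L)
    stopf("design infeasible: block_plates must be a multiple of both pool spans")

  i <- seq_len(n) - 1L                      # 0-based clone index
  wpp <- plate_rows * plate_cols
  plate <- i %/% wpp
  within <- i %% wpp
  row <- within %/% plate_cols              # 0-based
  col <- within %% plate_cols
  block <- plate %/% block_plates
  pib <- plate %% block_plates              # plate in block
  pair <- pib %/% plates_per_row_pool
  triple <- pib %/% plates_per_col_pool
  brow <- row %/% box_rows
  bcol <- col %/% box_cols

  row_pool <- sprintf("B%03d_R%d_%02d", block, pair, row)
  col_pool <- sprintf("B%03d_C%d_%02d", block, triple, col)
  box_pool <- sprintf("B%03d_X%d_%d_%d", block, pib, brow, bcol)

  triple_key <- paste(row_pool, col_pool, box_pool)
  if (anyDuplicated(triple_key))
    stopf("design infeasible: pool-triple map is not injective")

  tab <- data.frame(clone_id = clone_ids, block = block, plate = plate,
                    well_row = row, well_col = col,
                    row_pool = row_pool, col_pool = col_pool,
                    box_pool = box_pool)
  pools <- rbind(
    data.frame(pool_id = row_pool, block = block, dim = "row"),
    data.frame(pool_id = col_pool, block = block, dim = "col"),
    data.frame(pool_id = box_pool, block = block, dim = "box"))
  pools <- pools[!duplicated(pools$pool_id), , drop = FALSE]
  sizes <- table(c(row_pool, col_pool, box_pool))
  pools$size <- as.integer(sizes[pools$pool_id])
  pools <- pools[order(pools$pool_id), , drop = FALSE]
  rownames(pools) <- NULL

  structure(
    list(table = tab, pools = pools,
         geometry = list(plate_rows = plate_rows, plate_cols = plate_cols,
                         box_rows = box_rows, box_cols = box_cols,
                         plates_per_row_pool = plates_per_row_pool,
                         plates_per_col_pool = plates_per_col_pool,
                         block_plates = block_plates)),
    class = "wgp_pooling_design")
}

#' @export
print.wgp_pooling_design <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(paste0("wgp_pooling_design: %d clones, %d blocks, %d pools ",
                     "(plate %dx%d, box %dx%d, block %d plates)\n"),
              nrow(x$table), length(unique(x$table$block)), nrow(x$pools),
              g$plate_rows, g$plate_cols, g$box_rows, g$box_cols,
              g$block_plates))
  invisible(x)
}

#' Pools of a clone
#'
#' @param design a `wgp_pooling_design`.
#' @param clone_id one clone id.
#' @return named character triple `(row_pool, col_pool, box_pool)`.
#' @export
pools_of <- function(design, clone_id) {
  i <- match(clone_id, design$table$clone_id)
  if (is.na(i)) stopf("unknown clone `%s`", clone_id)
  c(row_pool = design$table$row_pool[i],
    col_pool = design$table$col_pool[i],
    box_pool = design$table$box_pool[i])
}

#' Resolve a pool triple to its clone
#'
#' Returns the unique clone lying in all three pools, or
#' `NA_character_` with attribute `status = "INCONSISTENT_TRIPLE"` when
#' the pools do not intersect (box on a plate outside the row pool's
#' plate pair or the column pool's plate triple, well outside the box's
#' sub-block, or pools from different blocks).  Unknown pool ids are an
#' error.
#'
#' @param design a `wgp_pooling_design`.
#' @param row_pool,col_pool,box_pool pool ids.
#' @return clone id, or tagged `NA_character_` on failure.
#' @export
resolve_triple <- function(design, row_pool, col_pool, box_pool) {
  ids <- c(row_pool, col_pool, box_pool)
  known <- ids %in% design$pools$pool_id
  if (!all(known))
    stopf("unknown pool id(s): %s", paste(ids[!known], collapse = ", "))
  t <- design$table
  hit <- t$row_pool == row_pool & t$col_pool == col_pool &
    t$box_pool == box_pool
  if (sum(hit) == 1L) return(t$clone_id[hit])
  structure(NA_character_, status = "INCONSISTENT_TRIPLE")
}

#' Rebuild a pooling design from its membership table
#'
#' Real-data mode: reconstructs a usable design object from a TSV-style
#' table (`clone_id`, `block`, `row_pool`, `col_pool`, `box_pool`), the
#' format [write_design_tsv()] emits and pooling providers supply.
#' Plate geometry is not recoverable (and not needed for
#' deconvolution); the triple map must still be injective.
#'
#' @param table data.frame with columns `clone_id`, `block`,
#'   `row_pool`, `col_pool`, `box_pool`.
#' @return a `wgp_pooling_design` (with `geometry = NULL`).
#' @export
design_from_table <- function(table) {
  need <- c("clone_id", "block", "row_pool", "col_pool", "box_pool")
  if (!all(need %in% names(table)))
    stopf("design table must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(table$clone_id)) stopf("clone ids must be unique")
  if (anyDuplicated(paste(table$row_pool, table$col_pool, table$box_pool)))
    stopf("design infeasible: pool-triple map is not injective")
  pools <- rbind(
    data.frame(pool_id = table$row_pool, block = table$block, dim = "row"),
    data.frame(pool_id = table$col_pool, block = table$block, dim = "col"),
    data.frame(pool_id = table$box_pool, block = table$block, dim = "box"))
  pools <- pools[!duplicated(pools$pool_id), , drop = FALSE]
  sizes <- table(c(table$row_pool, table$col_pool, table$box_pool))
  pools$size <- as.integer(sizes[pools$pool_id])
  pools <- pools[order(pools$pool_id), , drop = FALSE]
  rownames(pools) <- NULL
  structure(list(table = as.data.frame(table), pools = pools,
                 geometry = NULL),
            class = "wgp_pooling_design")
}

#' Write a pooling design as TSV
#'
#' Columns `clone_id`, `block`, `row_pool`, `col_pool`, `box_pool`.
#'
#' @param design a `wgp_pooling_design`.
#' @param path output path.
#' @export
write_design_tsv <- function(design, path) {
  write_tsv_file(design$table[, c("clone_id", "block", "row_pool",
                                  "col_pool", "box_pool")], path)
}
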