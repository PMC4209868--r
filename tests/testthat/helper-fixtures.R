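## Shared fixtures, built lazily and cached for the whole test run.
## The heavy pipeline (4000 shapes, the desk-scale study condition) is
## used by several acceptance checks; building it once keeps the suite
## fast without changing any study conditions.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

acc_grid <- function() fixture("grid", function() build_grid())

acc_stimuli <- function() fixture("stimuli", function() enumerate_stimuli())

## 4000-shape study condition: 70/30 split, 16x16 grid, five channels
acc_db <- function() fixture("db", function() sample_database(4000, seed = 20))

acc_features <- function() fixture("features", function() {
  feature_matrix(render_database(acc_db(), acc_grid()))
})

acc_split <- function() fixture("split", function() {
  db <- acc_db()
  list(train = which(db$split == "train"),
       validation = which(db$split == "validation"))
})

deriv_cols <- function(n = 16L) (n * n + 1L):(5L * n * n)

## exact Isomap (d = 8, k = 10) of the training derivatives plus
## out-of-sample coordinates for the validation shapes
acc_embedding <- function() fixture("embedding", function() {
  sp <- acc_split()
  deriv <- acc_features()[, deriv_cols()]
  emb <- isomap_fit(deriv[sp$train, , drop = FALSE], k = 10L, d = 8L)
  val_coords <- suppressWarnings(
    isomap_transform(emb, deriv[sp$validation, , drop = FALSE]))
  list(emb = emb, val_coords = val_coords)
})

## the 1200-shape scaled-down contrast condition: 840/360 of the same
## database, both target spaces, seeds 1:3
acc_contrast <- function() fixture("contrast", function() {
  sp <- acc_split()
  sub_tr <- sp$train[seq_len(840)]
  sub_va <- sp$validation[seq_len(360)]
  deriv <- acc_features()[, deriv_cols()]
  emb <- isomap_fit(deriv[sub_tr, , drop = FALSE], k = 10L, d = 8L)
  vco <- suppressWarnings(
    isomap_transform(emb, deriv[sub_va, , drop = FALSE]))
  Ysq <- db_parameters(acc_db())
  runs <- list()
  for (s in 1:3) {
    ni <- train_mlp(acc_features()[sub_tr, ], emb$coordinates, seed = s,
                    schedule = list(epochs = 30L, patience = 8L))
    ns <- train_mlp(acc_features()[sub_tr, ], Ysq[sub_tr, ], seed = s,
                    schedule = list(epochs = 30L, patience = 8L))
    runs[[s]] <- list(
      seed = s,
      isomap = evaluate_net(ni, acc_features()[sub_va, ], vco,
                            target_space = "isomap-8"),
      superquadric = evaluate_net(ns, acc_features()[sub_va, ],
                                  Ysq[sub_va, ],
                                  target_space = "superquadric-9"),
      net_isomap = ni, net_superquadric = ns)
  }
  list(runs = runs, sub_tr = sub_tr, sub_va = sub_va, emb = emb,
       val_coords = vco, Ysq = Ysq)
})

## a medium database with derivative features, for embedding diagnostics
db400 <- function() fixture("db400", function() {
  db <- sample_database(400, seed = 31)
  deriv <- feature_matrix(render_database(db, acc_grid()),
                          channels = c("dx", "dy", "dxx", "dyy"))
  list(db = db, deriv = deriv)
})

## analytic first-intersection / closest-approach depth for a centered
## sphere, per unit ray direction (the renderer's independent oracle)
sphere_ray_oracle <- function(dirs, radius, center = c(0, 0, 0.75)) {
  tproj <- as.numeric(dirs %*% center)
  disc <- tproj^2 - (sum(center^2) - radius^2)
  ifelse(disc >= 0, tproj - sqrt(pmax(disc, 0)), tproj)
}
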