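# Layer-by-layer parameter accounting for the eleven ImageNet backbones used
# in the screening benchmark. Each builder returns a data frame with one row
# per parameterised module (convolutions, batch norms, fully connected
# layers) so the total trainable-parameter count is an explicit structural
# sum, plus the penultimate width `d` feeding the classification head.
# The layer shapes follow the torchvision variants: SqueezeNet v1.1,
# GoogLeNet (Inception v1) without auxiliary heads, Inception v3 with its
# auxiliary branch (whose 1000-way auxiliary classifier is kept when only
# the main head is replaced, the standard fine-tuning idiom), MobileNetV2,
# DenseNet-121, EfficientNet B3/B7, ResNet-50, ResNeXt-50 32x4d and
# Wide ResNet-50-2 bottlenecks, and VGG-16 without batch norm.

p_conv <- function(name, cin, cout, k, bias = FALSE, groups = 1) {
  if (length(k) == 1) k <- c(k, k)
  data.frame(module = name,
             params = (k[1] * k[2] * cin / groups) * cout + if (bias) cout else 0)
}
p_bn <- function(name, c) data.frame(module = name, params = 2 * c)
p_fc <- function(name, din, dout, bias = TRUE)
  data.frame(module = name, params = din * dout + if (bias) dout else 0)

# conv (no bias) followed by batch norm -- the standard building block
p_cbn <- function(name, cin, cout, k, groups = 1)
  rbind(p_conv(name, cin, cout, k, bias = FALSE, groups = groups),
        p_bn(paste0(name, ".bn"), cout))

## ---- VGG-16 --------------------------------------------------------------
arch_vgg16 <- function() {
  cfg <- c(64, 64, NA, 128, 128, NA, 256, 256, 256, NA,
           512, 512, 512, NA, 512, 512, 512, NA)
  cin <- 3; rows <- list(); i <- 0
  for (v in cfg) {
    if (is.na(v)) next
    i <- i + 1
    rows[[length(rows) + 1]] <- p_conv(sprintf("features.conv%d", i),
                                       cin, v, 3, bias = TRUE)
    cin <- v
  }
  rows[[length(rows) + 1]] <- p_fc("classifier.fc1", 512 * 7 * 7, 4096)
  rows[[length(rows) + 1]] <- p_fc("classifier.fc2", 4096, 4096)
  list(layers = do.call(rbind, rows), d = 4096)
}

## ---- ResNet family -------------------------------------------------------
arch_resnet_bottleneck <- function(blocks = c(3, 4, 6, 3), groups = 1,
                                   base_width = 64) {
  rows <- list(p_cbn("conv1", 3, 64, 7))
  inplanes <- 64
  for (st in seq_along(blocks)) {
    planes <- 64 * 2^(st - 1)
    width <- floor(planes * base_width / 64) * groups
    out <- planes * 4
    for (b in seq_len(blocks[st])) {
      nm <- sprintf("layer%d.%d", st, b)
      rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".conv1"), inplanes, width, 1)
      rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".conv2"), width, width, 3,
                                        groups = groups)
      rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".conv3"), width, out, 1)
      if (b == 1)
        rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".downsample"),
                                          inplanes, out, 1)
      inplanes <- out
    }
  }
  list(layers = do.call(rbind, rows), d = 2048)
}

## ---- DenseNet-121 --------------------------------------------------------
arch_densenet121 <- function(growth = 32, blocks = c(6, 12, 24, 16),
                             bn_size = 4) {
  rows <- list(p_cbn("features.conv0", 3, 64, 7))
  ch <- 64
  for (bl in seq_along(blocks)) {
    for (l in seq_len(blocks[bl])) {
      nm <- sprintf("denseblock%d.layer%d", bl, l)
      rows[[length(rows) + 1]] <- p_bn(paste0(nm, ".norm1"), ch)
      rows[[length(rows) + 1]] <- p_conv(paste0(nm, ".conv1"), ch,
                                         bn_size * growth, 1)
      rows[[length(rows) + 1]] <- p_bn(paste0(nm, ".norm2"), bn_size * growth)
      rows[[length(rows) + 1]] <- p_conv(paste0(nm, ".conv2"),
                                         bn_size * growth, growth, 3)
      ch <- ch + growth
    }
    if (bl < length(blocks)) {
      nm <- sprintf("transition%d", bl)
      rows[[length(rows) + 1]] <- p_bn(paste0(nm, ".norm"), ch)
      rows[[length(rows) + 1]] <- p_conv(paste0(nm, ".conv"), ch, ch %/% 2, 1)
      ch <- ch %/% 2
    }
  }
  rows[[length(rows) + 1]] <- p_bn("features.norm5", ch)
  list(layers = do.call(rbind, rows), d = ch)
}

## ---- SqueezeNet v1.1 -----------------------------------------------------
arch_squeezenet11 <- function() {
  fire <- function(nm, cin, s, e) rbind(
    p_conv(paste0(nm, ".squeeze"), cin, s, 1, bias = TRUE),
    p_conv(paste0(nm, ".expand1x1"), s, e, 1, bias = TRUE),
    p_conv(paste0(nm, ".expand3x3"), s, e, 3, bias = TRUE))
  rows <- list(p_conv("features.conv1", 3, 64, 3, bias = TRUE),
               fire("fire2", 64, 16, 64), fire("fire3", 128, 16, 64),
               fire("fire4", 128, 32, 128), fire("fire5", 256, 32, 128),
               fire("fire6", 256, 48, 192), fire("fire7", 384, 48, 192),
               fire("fire8", 384, 64, 256), fire("fire9", 512, 64, 256))
  # classifier is a 1x1 conv with bias: d*classes + classes parameters,
  # identical arithmetic to a dense head
  list(layers = do.call(rbind, rows), d = 512)
}

## ---- MobileNetV2 ---------------------------------------------------------
arch_mobilenetv2 <- function() {
  settings <- list(c(1, 16, 1), c(6, 24, 2), c(6, 32, 3), c(6, 64, 4),
                   c(6, 96, 3), c(6, 160, 3), c(6, 320, 1))
  rows <- list(p_cbn("features.0", 3, 32, 3))
  cin <- 32; bi <- 0
  for (s in settings) {
    t <- s[1]; cout <- s[2]; n <- s[3]
    for (b in seq_len(n)) {
      bi <- bi + 1
      nm <- sprintf("invres%d", bi)
      hid <- cin * t
      if (t != 1)
        rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".expand"), cin, hid, 1)
      rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".dw"), hid, hid, 3,
                                        groups = hid)
      rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".project"), hid, cout, 1)
      cin <- cout
    }
  }
  rows[[length(rows) + 1]] <- p_cbn("features.last", cin, 1280, 1)
  list(layers = do.call(rbind, rows), d = 1280)
}

## ---- GoogLeNet (Inception v1, no auxiliary heads) ------------------------
arch_googlenet <- function() {
  # torchvision uses 3x3 kernels on the "5x5" branch
  inc <- function(nm, cin, c1, c3r, c3, c5r, c5, pp) rbind(
    p_cbn(paste0(nm, ".branch1"), cin, c1, 1),
    p_cbn(paste0(nm, ".branch2.reduce"), cin, c3r, 1),
    p_cbn(paste0(nm, ".branch2.conv"), c3r, c3, 3),
    p_cbn(paste0(nm, ".branch3.reduce"), cin, c5r, 1),
    p_cbn(paste0(nm, ".branch3.conv"), c5r, c5, 3),
    p_cbn(paste0(nm, ".branch4.proj"), cin, pp, 1))
  rows <- list(
    p_cbn("conv1", 3, 64, 7), p_cbn("conv2", 64, 64, 1),
    p_cbn("conv3", 64, 192, 3),
    inc("3a", 192, 64, 96, 128, 16, 32, 32),
    inc("3b", 256, 128, 128, 192, 32, 96, 64),
    inc("4a", 480, 192, 96, 208, 16, 48, 64),
    inc("4b", 512, 160, 112, 224, 24, 64, 64),
    inc("4c", 512, 128, 128, 256, 24, 64, 64),
    inc("4d", 512, 112, 144, 288, 32, 64, 64),
    inc("4e", 528, 256, 160, 320, 32, 128, 128),
    inc("5a", 832, 256, 160, 320, 32, 128, 128),
    inc("5b", 832, 384, 192, 384, 48, 128, 128))
  list(layers = do.call(rbind, rows), d = 1024)
}

## ---- Inception v3 (with auxiliary branch) --------------------------------
arch_inception3 <- function(aux_classes = 1000) {
  ia <- function(nm, cin, pf) rbind(
    p_cbn(paste0(nm, ".b1x1"), cin, 64, 1),
    p_cbn(paste0(nm, ".b5x5.1"), cin, 48, 1),
    p_cbn(paste0(nm, ".b5x5.2"), 48, 64, 5),
    p_cbn(paste0(nm, ".b3dbl.1"), cin, 64, 1),
    p_cbn(paste0(nm, ".b3dbl.2"), 64, 96, 3),
    p_cbn(paste0(nm, ".b3dbl.3"), 96, 96, 3),
    p_cbn(paste0(nm, ".pool"), cin, pf, 1))
  ib <- function(nm, cin) rbind(
    p_cbn(paste0(nm, ".b3x3"), cin, 384, 3),
    p_cbn(paste0(nm, ".b3dbl.1"), cin, 64, 1),
    p_cbn(paste0(nm, ".b3dbl.2"), 64, 96, 3),
    p_cbn(paste0(nm, ".b3dbl.3"), 96, 96, 3))
  ic <- function(nm, cin, c7) rbind(
    p_cbn(paste0(nm, ".b1x1"), cin, 192, 1),
    p_cbn(paste0(nm, ".b7.1"), cin, c7, 1),
    p_cbn(paste0(nm, ".b7.2"), c7, c7, c(1, 7)),
    p_cbn(paste0(nm, ".b7.3"), c7, 192, c(7, 1)),
    p_cbn(paste0(nm, ".b7dbl.1"), cin, c7, 1),
    p_cbn(paste0(nm, ".b7dbl.2"), c7, c7, c(7, 1)),
    p_cbn(paste0(nm, ".b7dbl.3"), c7, c7, c(1, 7)),
    p_cbn(paste0(nm, ".b7dbl.4"), c7, c7, c(7, 1)),
    p_cbn(paste0(nm, ".b7dbl.5"), c7, 192, c(1, 7)),
    p_cbn(paste0(nm, ".pool"), cin, 192, 1))
  id <- function(nm, cin) rbind(
    p_cbn(paste0(nm, ".b3x3.1"), cin, 192, 1),
    p_cbn(paste0(nm, ".b3x3.2"), 192, 320, 3),
    p_cbn(paste0(nm, ".b7x7x3.1"), cin, 192, 1),
    p_cbn(paste0(nm, ".b7x7x3.2"), 192, 192, c(1, 7)),
    p_cbn(paste0(nm, ".b7x7x3.3"), 192, 192, c(7, 1)),
    p_cbn(paste0(nm, ".b7x7x3.4"), 192, 192, 3))
  ie <- function(nm, cin) rbind(
    p_cbn(paste0(nm, ".b1x1"), cin, 320, 1),
    p_cbn(paste0(nm, ".b3.1"), cin, 384, 1),
    p_cbn(paste0(nm, ".b3.2a"), 384, 384, c(1, 3)),
    p_cbn(paste0(nm, ".b3.2b"), 384, 384, c(3, 1)),
    p_cbn(paste0(nm, ".b3dbl.1"), cin, 448, 1),
    p_cbn(paste0(nm, ".b3dbl.2"), 448, 384, 3),
    p_cbn(paste0(nm, ".b3dbl.3a"), 384, 384, c(1, 3)),
    p_cbn(paste0(nm, ".b3dbl.3b"), 384, 384, c(3, 1)),
    p_cbn(paste0(nm, ".pool"), cin, 192, 1))
  rows <- list(
    p_cbn("Conv2d_1a", 3, 32, 3), p_cbn("Conv2d_2a", 32, 32, 3),
    p_cbn("Conv2d_2b", 32, 64, 3), p_cbn("Conv2d_3b", 64, 80, 1),
    p_cbn("Conv2d_4a", 80, 192, 3),
    ia("Mixed_5b", 192, 32), ia("Mixed_5c", 256, 64), ia("Mixed_5d", 288, 64),
    ib("Mixed_6a", 288),
    ic("Mixed_6b", 768, 128), ic("Mixed_6c", 768, 160),
    ic("Mixed_6d", 768, 160), ic("Mixed_6e", 768, 192),
    p_cbn("AuxLogits.conv0", 768, 128, 1),
    p_cbn("AuxLogits.conv1", 128, 768, 5),
    p_fc("AuxLogits.fc", 768, aux_classes),
    id("Mixed_7a", 768),
    ie("Mixed_7b", 1280), ie("Mixed_7c", 2048))
  list(layers = do.call(rbind, rows), d = 2048)
}

## ---- EfficientNet (B3, B7) -----------------------------------------------
make_divisible <- function(v, divisor = 8) {
  new_v <- max(divisor, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  new_v
}

arch_efficientnet <- function(width_mult, depth_mult) {
  adjc <- function(ch) make_divisible(ch * width_mult)
  base <- list(  # expand, kernel, in, out, repeats (B0 stage settings)
    c(1, 3, 32, 16, 1), c(6, 3, 16, 24, 2), c(6, 5, 24, 40, 2),
    c(6, 3, 40, 80, 3), c(6, 5, 80, 112, 3), c(6, 5, 112, 192, 4),
    c(6, 3, 192, 320, 1))
  rows <- list(p_cbn("features.stem", 3, adjc(32), 3))
  bi <- 0
  for (s in base) {
    e <- s[1]; k <- s[2]
    cin <- adjc(s[3]); cout <- adjc(s[4])
    reps <- ceiling(s[5] * depth_mult)
    for (b in seq_len(reps)) {
      bi <- bi + 1
      nm <- sprintf("mbconv%d", bi)
      bl_in <- if (b == 1) cin else cout
      exp <- make_divisible(bl_in * e)
      if (exp != bl_in)
        rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".expand"), bl_in, exp, 1)
      rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".dw"), exp, exp, k,
                                        groups = exp)
      sq <- max(1, bl_in %/% 4)   # squeeze-excitation on pre-expansion width
      rows[[length(rows) + 1]] <- p_conv(paste0(nm, ".se.fc1"), exp, sq, 1,
                                         bias = TRUE)
      rows[[length(rows) + 1]] <- p_conv(paste0(nm, ".se.fc2"), sq, exp, 1,
                                         bias = TRUE)
      rows[[length(rows) + 1]] <- p_cbn(paste0(nm, ".project"), exp, cout, 1)
    }
  }
  last_in <- adjc(320)
  rows[[length(rows) + 1]] <- p_cbn("features.head", last_in, 4 * last_in, 1)
  list(layers = do.call(rbind, rows), d = 4 * last_in)
}

## ---- registry ------------------------------------------------------------

#' Supported backbone architectures
#' @return character vector of architecture names accepted by
#'   [model_spec()].
#' @export
supported_archs <- function() c(
  "SqueezeNet", "MobileNetv2", "Inceptionv1", "DenseNet121",
  "EfficientNet-B3", "ResNeXt50", "ResNet50", "Inceptionv3",
  "EfficientNet-B7", "WideResNet50", "VGG16")

arch_backbone <- function(arch_name) {
  switch(arch_name,
    "SqueezeNet"      = arch_squeezenet11(),
    "MobileNetv2"     = arch_mobilenetv2(),
    "Inceptionv1"     = arch_googlenet(),
    "DenseNet121"     = arch_densenet121(),
    "EfficientNet-B3" = arch_efficientnet(1.2, 1.4),
    "ResNeXt50"       = arch_resnet_bottleneck(groups = 32, base_width = 4),
    "ResNet50"        = arch_resnet_bottleneck(),
    "Inceptionv3"     = arch_inception3(),
    "EfficientNet-B7" = arch_efficientnet(2.0, 3.1),
    "WideResNet50"    = arch_resnet_bottleneck(base_width = 128),
    "VGG16"           = arch_vgg16(),
    stop("unknown architecture: ", arch_name)
  )
}
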