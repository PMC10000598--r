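// Minimal 16-bit grayscale PNG codec (the CRAN `png` package cannot write
// 16-bit).  Only the subset needed for depth frames is supported: one
// channel, bit depth 16, no interlace, filter type 0 per scanline on write;
// filters 0-4 are understood on read.  Compression via zlib (system).

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>

using namespace Rcpp;

static const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

static void put_u32(std::vector<unsigned char> &v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static uint32_t get_u32(const unsigned char *p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void write_chunk(std::vector<unsigned char> &out, const char *type,
                        const unsigned char *data, size_t len) {
  put_u32(out, (uint32_t)len);
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  if (len) out.insert(out.end(), data, data + len);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(len + 4));
  put_u32(out, (uint32_t)crc);
}

// [[Rcpp::export(name = ".png16_write")]]
void png16_write(std::string path, IntegerMatrix z) {
  int h = z.nrow(), w = z.ncol();
  // raw scanlines: filter byte 0 + big-endian uint16 per pixel
  std::vector<unsigned char> raw((size_t)h * (1 + 2 * (size_t)w));
  size_t k = 0;
  for (int r = 0; r < h; ++r) {
    raw[k++] = 0;
    for (int c = 0; c < w; ++c) {
      int val = z(r, c);
      if (val == NA_INTEGER || val < 0) val = 0;
      if (val > 65535) val = 65535;
      raw[k++] = (val >> 8) & 0xff;
      raw[k++] = val & 0xff;
    }
  }
  uLongf clen = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("PNG deflate failed");
  comp.resize(clen);

  std::vector<unsigned char> out;
  out.insert(out.end(), PNG_SIG, PNG_SIG + 8);
  unsigned char ihdr[13];
  ihdr[0] = (w >> 24) & 0xff; ihdr[1] = (w >> 16) & 0xff;
  ihdr[2] = (w >> 8) & 0xff;  ihdr[3] = w & 0xff;
  ihdr[4] = (h >> 24) & 0xff; ihdr[5] = (h >> 16) & 0xff;
  ihdr[6] = (h >> 8) & 0xff;  ihdr[7] = h & 0xff;
  ihdr[8] = 16;  // bit depth
  ihdr[9] = 0;   // color type: grayscale
  ihdr[10] = 0; ihdr[11] = 0; ihdr[12] = 0;
  write_chunk(out, "IHDR", ihdr, 13);
  write_chunk(out, "IDAT", comp.data(), comp.size());
  write_chunk(out, "IEND", NULL, 0);

  FILE *f = fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  size_t n = fwrite(out.data(), 1, out.size(), f);
  fclose(f);
  if (n != out.size()) stop("short write to '%s'", path.c_str());
}

static int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b),
      pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export(name = ".png16_read")]]
IntegerMatrix png16_read(std::string path) {
  FILE *f = fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  fseek(f, 0, SEEK_END);
  long sz = ftell(f);
  fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf((size_t)sz);
  if (fread(buf.data(), 1, (size_t)sz, f) != (size_t)sz) {
    fclose(f);
    stop("short read from '%s'", path.c_str());
  }
  fclose(f);
  if (sz < 8 || memcmp(buf.data(), PNG_SIG, 8) != 0)
    stop("'%s' is not a PNG file", path.c_str());

  size_t pos = 8;
  int w = 0, h = 0, depth = 0, color = -1, interlace = 0;
  std::vector<unsigned char> idat;
  while (pos + 8 <= (size_t)sz) {
    uint32_t len = get_u32(&buf[pos]);
    char type[5] = {0};
    memcpy(type, &buf[pos + 4], 4);
    const unsigned char *data = &buf[pos + 8];
    if (pos + 12 + len > (size_t)sz) stop("corrupt PNG chunk");
    if (strcmp(type, "IHDR") == 0) {
      w = (int)get_u32(data);
      h = (int)get_u32(data + 4);
      depth = data[8];
      color = data[9];
      interlace = data[12];
    } else if (strcmp(type, "IDAT") == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (strcmp(type, "IEND") == 0) {
      break;
    }
    pos += 12 + len;
  }
  if (color != 0 || depth != 16)
    stop("unsupported depth encoding (need 16-bit single-channel grayscale)");
  if (interlace != 0) stop("interlaced PNG not supported");
  if (w <= 0 || h <= 0) stop("corrupt PNG header");

  size_t stride = 2 * (size_t)w;
  size_t rawlen = (size_t)h * (1 + stride);
  std::vector<unsigned char> raw(rawlen);
  uLongf dlen = (uLongf)rawlen;
  int rc = uncompress(raw.data(), &dlen, idat.data(), (uLong)idat.size());
  if (rc != Z_OK || dlen != rawlen) stop("PNG inflate failed");

  // de-filter (bpp = 2)
  IntegerMatrix z(h, w);
  std::vector<unsigned char> prev(stride, 0), cur(stride);
  for (int r = 0; r < h; ++r) {
    unsigned char ft = raw[(size_t)r * (1 + stride)];
    const unsigned char *line = &raw[(size_t)r * (1 + stride) + 1];
    for (size_t i = 0; i < stride; ++i) {
      int a = i >= 2 ? cur[i - 2] : 0;
      int b = prev[i];
      int c = i >= 2 ? prev[i - 2] : 0;
      int x = line[i];
      switch (ft) {
        case 0: break;
        case 1: x += a; break;
        case 2: x += b; break;
        case 3: x += (a + b) / 2; break;
        case 4: x += paeth(a, b, c); break;
        default: stop("unsupported PNG filter type %d", (int)ft);
      }
      cur[i] = (unsigned char)(x & 0xff);
    }
    for (int cidx = 0; cidx < w; ++cidx)
      z(r, cidx) = ((int)cur[2 * cidx] << 8) | (int)cur[2 * cidx + 1];
    prev = cur;
  }
  return z;
}
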