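# The conda toolchain targets its bundled glibc-2.39 sysroot, which is newer
# than the runtime glibc; build against the system sysroot instead so the
# shared object loads.
PKG_CPPFLAGS = --sysroot=/ -I/usr/include/x86_64-linux-gnu
PKG_LIBS = --sysroot=/ -B/usr/lib/x86_64-linux-gnu -L/usr/lib/x86_64-linux-gnu
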