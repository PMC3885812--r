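# The conda toolchain in this image targets glibc 2.39 while the system
# runtime loader is glibc 2.35, so objects built with it cannot be loaded.
# Force the system compiler (which targets the system glibc) for this
# package's compiled code. `override` is needed because this file is
# included before R's Makeconf.
override CXX = g++
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
override CXX20 = g++
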