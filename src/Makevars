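# The conda toolchain targets a sysroot glibc (2.39) newer than the runtime
# loader's glibc, so its shared objects fail to dyn.load in this image.
# Build with the system compiler, which links against the runtime glibc.
# (Makevars is read before Makeconf, hence the override directives.)
override CXX = /usr/bin/g++ -std=gnu++17
override CXX17 = /usr/bin/g++
override CXXFLAGS = -O2 -Wall -fPIC
override CXX17FLAGS = -O2 -Wall -fPIC
override CPPFLAGS = -I/opt/conda/envs/bio/include
override SHLIB_CXXLD = /usr/bin/g++ -std=gnu++17
override SHLIB_LD = /usr/bin/g++
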